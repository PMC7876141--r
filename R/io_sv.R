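# SSV input/output: Manta-style VCF (with BND mate pairing) and 10+ column
# BEDPE. Internal coordinates are 0-based half-open; VCF positions are
# converted on read (breakends of symbolic records sit at POS-1 and END-1).
#
# Breakend orientation convention used throughout the package:
#   positive = the sequence upstream of the breakpoint (lower coordinates)
#              is retained / fused at the junction;
#   negative = the downstream sequence (higher coordinates) is retained.
# For VCF BND records this is derived from bracket notation: the local
# breakend is positive when the reference base precedes the bracket
# (t[p[ or t]p]); the mate is positive for ']' (piece left of p) and
# negative for '[' (piece right of p).

.default_strands <- c(deletion = "+-", duplication = "-+",
                      insertion = "+-", inversion = "++")

.orient_from_char <- function(ch) ifelse(ch == "+", "positive", "negative")
.char_from_orient <- function(o) ifelse(o == "positive", "+", "-")

#' Read somatic structural variants from a VCF file
#'
#' Parses an SV VCF (SVTYPE in INFO, BND records paired via MATEID) into a
#' mate-merged SSV table: each translocation's two breakend entries become a
#' single record, so downstream burden counts treat them as one event.
#'
#' Tumor assignment: a cohort VCF may carry the tumor in the `TID` INFO
#' field; otherwise supply `tumor_id` for a per-tumor VCF.
#'
#' @param path VCF file path.
#' @param pass_only Drop records whose FILTER is not PASS (or `.`)?
#' @param tumor_id Tumor identifier used when the VCF lacks a `TID` INFO
#'   field.
#' @param drop_noncanonical Drop records touching non-canonical chromosomes
#'   (anything outside chr1-chr22, chrX, chrY, with or without the "chr"
#'   prefix), with a reported count.
#' @return A `data.frame` with columns `ssv_id`, `svclass`, `chrom1`, `pos1`,
#'   `orient1`, `chrom2`, `pos2`, `orient2`, `tumor_id`, `pass_filter`;
#'   positions 0-based.
#' @export
read_sv_vcf <- function(path, pass_only = TRUE, tumor_id = NULL,
                        drop_noncanonical = TRUE) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  n <- length(vcf)
  if (n == 0L) return(.empty_ssv_df())

  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  svtype <- as.character(info$SVTYPE)
  .assert(!is.null(info$SVTYPE), "VCF has no SVTYPE INFO field")

  filt <- as.character(rr$FILTER)
  pass <- filt %in% c("PASS", ".")
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos1based <- GenomicRanges::start(rr)
  ids <- names(rr)

  tid <- if (!is.null(info$TID)) as.character(info$TID) else {
    .assert(!is.null(tumor_id),
            "VCF lacks a TID INFO field; supply tumor_id=")
    rep(tumor_id, n)
  }

  end1based <- if (!is.null(info$END)) suppressWarnings(as.integer(info$END)) else rep(NA_integer_, n)
  strands <- if (!is.null(info$STRANDS)) as.character(info$STRANDS) else rep(NA_character_, n)
  mateid <- if (!is.null(info$MATEID)) {
    m <- info$MATEID
    if (methods::is(m, "CharacterList")) {
      vapply(m, function(x) if (length(x)) x[[1]] else NA_character_, "")
    } else as.character(m)
  } else rep(NA_character_, n)

  alt <- VariantAnnotation::alt(vcf)
  alt <- if (methods::is(alt, "CharacterList") || methods::is(alt, "List")) {
    vapply(as.list(alt), function(x) if (length(x)) as.character(x)[1] else "", "")
  } else as.character(alt)

  if (pass_only) {
    keep <- pass
    svtype <- svtype[keep]; chrom <- chrom[keep]; pos1based <- pos1based[keep]
    ids <- ids[keep]; tid <- tid[keep]; end1based <- end1based[keep]
    strands <- strands[keep]; mateid <- mateid[keep]; alt <- alt[keep]
    pass <- pass[keep]
  }
  if (length(svtype) == 0L) return(.empty_ssv_df())

  is_bnd <- svtype == "BND"
  out <- list()

  # --- symbolic (intra-chromosomal) records ---------------------------------
  if (any(!is_bnd)) {
    i <- which(!is_bnd)
    cls <- c(DEL = "deletion", DUP = "duplication", INS = "insertion",
             INV = "inversion")[svtype[i]]
    .assert(!anyNA(cls), "unsupported SVTYPE value(s): %s",
            paste(unique(svtype[i][is.na(cls)]), collapse = ","))
    e <- end1based[i]
    .assert(!anyNA(e), "non-BND SV record without END INFO field")
    st <- strands[i]
    st[is.na(st)] <- .default_strands[cls][is.na(st)]
    out$sym <- data.frame(
      ssv_id = ids[i], svclass = unname(cls),
      chrom1 = chrom[i], pos1 = pos1based[i] - 1L,
      orient1 = .orient_from_char(substr(st, 1, 1)),
      chrom2 = chrom[i], pos2 = e - 1L,
      orient2 = .orient_from_char(substr(st, 2, 2)),
      tumor_id = tid[i], pass_filter = pass[i],
      stringsAsFactors = FALSE
    )
  }

  # --- BND mate pairs -------------------------------------------------------
  if (any(is_bnd)) {
    i <- which(is_bnd)
    m <- regmatches(alt[i], regexec("([][])([^:]+):([0-9]+)([][])", alt[i],
                                    perl = TRUE))
    ok <- lengths(m) == 5L
    .assert(all(ok), "malformed BND ALT for record(s): %s",
            paste(utils::head(ids[i][!ok], 5), collapse = ","))
    bracket <- vapply(m, `[`, "", 2L)
    local_first <- !startsWith(alt[i], "[") & !startsWith(alt[i], "]")
    local_orient <- ifelse(local_first, "positive", "negative")
    mate_orient <- ifelse(bracket == "]", "positive", "negative")

    bnd <- data.frame(
      id = ids[i], mate = mateid[i], chrom = chrom[i],
      pos = pos1based[i] - 1L, orient = local_orient,
      mate_orient = mate_orient, tumor_id = tid[i], pass = pass[i],
      stringsAsFactors = FALSE
    )
    have_mate <- !is.na(bnd$mate) & bnd$mate %in% bnd$id
    n_drop <- sum(!have_mate)
    if (n_drop > 0L) {
      warning(sprintf("dropped %d unpaired BND record(s)", n_drop),
              call. = FALSE)
      bnd <- bnd[have_mate, , drop = FALSE]
    }
    if (nrow(bnd) > 0L) {
      rownames(bnd) <- bnd$id
      # deterministic primary: lexicographically smaller (chrom,pos,id)
      key <- paste(bnd$chrom, formatC(bnd$pos, width = 12, flag = "0"), bnd$id)
      primary <- key < key[match(bnd$mate, bnd$id)]
      p <- bnd[primary, , drop = FALSE]
      q <- bnd[match(p$mate, bnd$id), , drop = FALSE]
      cls <- ifelse(p$chrom != q$chrom, "translocation",
              ifelse(p$orient == q$orient, "inversion",
               ifelse(p$orient == "positive", "deletion", "duplication")))
      out$bnd <- data.frame(
        ssv_id = sub("_[12]$", "", p$id), svclass = cls,
        chrom1 = p$chrom, pos1 = p$pos, orient1 = p$orient,
        chrom2 = q$chrom, pos2 = q$pos, orient2 = q$orient,
        tumor_id = p$tumor_id, pass_filter = p$pass,
        stringsAsFactors = FALSE
      )
    }
  }

  ssvs <- do.call(rbind, unname(out))
  if (is.null(ssvs) || nrow(ssvs) == 0L) return(.empty_ssv_df())
  rownames(ssvs) <- NULL

  if (drop_noncanonical) {
    keep <- .is_canonical(ssvs$chrom1) & .is_canonical(ssvs$chrom2)
    if (any(!keep)) {
      message(sprintf("dropped %d SSV(s) on non-canonical chromosomes",
                      sum(!keep)))
      ssvs <- ssvs[keep, , drop = FALSE]
    }
  }
  .check_ssv_df(ssvs)
  ssvs
}

.empty_ssv_df <- function() {
  data.frame(ssv_id = character(), svclass = character(),
             chrom1 = character(), pos1 = integer(), orient1 = character(),
             chrom2 = character(), pos2 = integer(), orient2 = character(),
             tumor_id = character(), pass_filter = logical(),
             stringsAsFactors = FALSE)
}

#' Write SSV records to a cohort VCF
#'
#' Inverse of [read_sv_vcf()]. Intra-chromosomal classes are written as
#' symbolic ALT records (`<DEL>` etc.) with `END` and `STRANDS`;
#' translocations as two mate-paired BND lines whose bracket notation encodes
#' both breakend orientations. The tumor goes into the `TID` INFO field.
#'
#' @param ssvs SSV table as returned by [read_sv_vcf()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(ssvs, path) {
  .check_ssv_df(ssvs)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"ID of mate breakend\">",
    "##INFO=<ID=STRANDS,Number=1,Type=String,Description=\"Breakend orientations\">",
    "##INFO=<ID=TID,Number=1,Type=String,Description=\"Tumor sample identifier\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  lines <- character(0)
  filt <- ifelse(ssvs$pass_filter, "PASS", "MinQual")
  tra <- ssvs$svclass == "translocation"
  if (any(!tra)) {
    i <- which(!tra)
    sym <- c(deletion = "DEL", duplication = "DUP", insertion = "INS",
             inversion = "INV")[ssvs$svclass[i]]
    st <- paste0(.char_from_orient(ssvs$orient1[i]),
                 .char_from_orient(ssvs$orient2[i]))
    lines <- c(lines, sprintf(
      "%s\t%d\t%s\tN\t<%s>\t.\t%s\tSVTYPE=%s;END=%d;STRANDS=%s;TID=%s",
      ssvs$chrom1[i], ssvs$pos1[i] + 1L, ssvs$ssv_id[i], sym, filt[i],
      sym, ssvs$pos2[i] + 1L, st, ssvs$tumor_id[i]))
  }
  if (any(tra)) {
    i <- which(tra)
    id1 <- paste0(ssvs$ssv_id[i], "_1")
    id2 <- paste0(ssvs$ssv_id[i], "_2")
    alt1 <- .bnd_alt(ssvs$orient1[i], ssvs$orient2[i],
                     ssvs$chrom2[i], ssvs$pos2[i] + 1L)
    alt2 <- .bnd_alt(ssvs$orient2[i], ssvs$orient1[i],
                     ssvs$chrom1[i], ssvs$pos1[i] + 1L)
    lines <- c(lines,
      sprintf("%s\t%d\t%s\tN\t%s\t.\t%s\tSVTYPE=BND;MATEID=%s;TID=%s",
              ssvs$chrom1[i], ssvs$pos1[i] + 1L, id1, alt1, filt[i],
              id2, ssvs$tumor_id[i]),
      sprintf("%s\t%d\t%s\tN\t%s\t.\t%s\tSVTYPE=BND;MATEID=%s;TID=%s",
              ssvs$chrom2[i], ssvs$pos2[i] + 1L, id2, alt2, filt[i],
              id1, ssvs$tumor_id[i]))
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

# Bracket-notation ALT for a breakend whose local orientation is
# local_orient, referencing a mate with orientation mate_orient.
.bnd_alt <- function(local_orient, mate_orient, mate_chrom, mate_pos1based) {
  br <- ifelse(mate_orient == "positive", "]", "[")
  ref_first <- local_orient == "positive"
  ifelse(ref_first,
         sprintf("N%s%s:%d%s", br, mate_chrom, mate_pos1based, br),
         sprintf("%s%s:%d%sN", br, mate_chrom, mate_pos1based, br))
}

#' Read or write SSV records as BEDPE
#'
#' The dialect is 10-column BEDPE (chrom1, start1, end1, chrom2, start2,
#' end2, name, score, strand1, strand2) plus three extra columns: `svclass`,
#' `tumor_id`, `pass_filter`. Strands encode breakend orientation
#' (`+` = upstream sequence retained). Coordinates are 0-based half-open;
#' each breakend occupies a 1-bp interval.
#'
#' @param path BEDPE file path.
#' @param ssvs SSV table (see [read_sv_vcf()]).
#' @return `read_sv_bedpe`: an SSV `data.frame`; `write_sv_bedpe`: `path`,
#'   invisibly.
#' @export
read_sv_bedpe <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  .assert(ncol(d) >= 13L, "BEDPE must have 13 columns (10 + svclass, tumor_id, pass_filter)")
  ssvs <- data.frame(
    ssv_id = as.character(d[[7]]), svclass = as.character(d[[11]]),
    chrom1 = as.character(d[[1]]), pos1 = as.integer(d[[2]]),
    orient1 = .orient_from_char(as.character(d[[9]])),
    chrom2 = as.character(d[[4]]), pos2 = as.integer(d[[5]]),
    orient2 = .orient_from_char(as.character(d[[10]])),
    tumor_id = as.character(d[[12]]), pass_filter = as.logical(d[[13]]),
    stringsAsFactors = FALSE
  )
  .check_ssv_df(ssvs)
}

#' @rdname read_sv_bedpe
#' @export
write_sv_bedpe <- function(ssvs, path) {
  .check_ssv_df(ssvs)
  d <- data.frame(
    ssvs$chrom1, ssvs$pos1, ssvs$pos1 + 1L,
    ssvs$chrom2, ssvs$pos2, ssvs$pos2 + 1L,
    ssvs$ssv_id, ".",
    .char_from_orient(ssvs$orient1), .char_from_orient(ssvs$orient2),
    ssvs$svclass, ssvs$tumor_id, ssvs$pass_filter
  )
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
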