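#' Hamming distance between equal-length DNA strings
#'
#' Case-insensitive positional mismatch count; any non-ACGT character counts
#' as a mismatch.
#'
#' @param a,b DNA strings of equal length.
#' @return integer mismatch count.
#' @export
#' @examples
#' count_mismatches("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGA")
count_mismatches <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("strings must have equal length")
  ca <- chars(a); cb <- chars(b)
  sum(ca != cb | !(ca %in% DNA_BASES) | !(cb %in% DNA_BASES))
}

#' Match a 3-nt PAM against an IUPAC pattern
#'
#' @param seq observed 3-nt sequence.
#' @param pattern 3-symbol IUPAC pattern (e.g. `"NGG"`, `"NGN"`).
#' @return logical.
#' @export
#' @examples
#' pam_match("AGG", "NGG")
#' pam_match("TGA", "NGN")
pam_match <- function(seq, pattern) {
  seq <- toupper(seq); pattern <- toupper(pattern)
  if (nchar(seq) != 3 || nchar(pattern) != 3) stop("seq and pattern must be 3 nt")
  ps <- chars(pattern)
  bad <- setdiff(ps, names(IUPAC_CLASSES))
  if (length(bad) > 0) stop("non-IUPAC symbol in pattern: ", bad[1])
  ss <- chars(seq)
  all(vapply(1:3, function(i) ss[i] %in% IUPAC_CLASSES[[ps[i]]], logical(1)))
}

# Per-position IUPAC membership over an integer-coded chromosome, vectorized.
iupac_hits <- function(code, sym) {
  allowed <- utf8ToInt(paste(IUPAC_CLASSES[[sym]], collapse = ""))
  code %in% allowed
}

# Scan one strand of one chromosome for <= max_mm matches to `proto` with an
# adjacent PAM. `seq` is the sequence in the orientation being scanned;
# returns 0-based offsets (in that orientation) of the protospacer start,
# with mismatch counts and observed PAMs.
scan_strand <- function(seq, proto, max_mm, pam_pattern) {
  L <- nchar(seq)
  if (L < 23) return(NULL)
  code <- utf8ToInt(seq)
  pr <- utf8ToInt(proto)
  acgt <- utf8ToInt("ACGT")
  n_start <- L - 23L + 1L  # protospacer start positions leaving room for PAM
  mm <- integer(n_start)
  for (j in 1:20) {
    win <- code[j:(j + n_start - 1L)]
    mm <- mm + as.integer(win != pr[j] | !(win %in% acgt))
  }
  ps <- chars(toupper(pam_pattern))
  ok <- rep(TRUE, n_start)
  for (k in 1:3) {
    win <- code[(20L + k):(20L + k + n_start - 1L)]
    ok <- ok & iupac_hits(win, ps[k])
  }
  hit <- which(mm <= max_mm & ok)
  if (length(hit) == 0) return(NULL)
  data.frame(offset = hit - 1L, mismatch_count = mm[hit],
             pam = substring(seq, hit + 20L, hit + 22L),
             seq = substring(seq, hit, hit + 19L),
             stringsAsFactors = FALSE)
}

#' Enumerate candidate off-target sites in a genome
#'
#' Scans both strands of every chromosome for 20-nt windows within `max_mm`
#' mismatches of each gRNA protospacer and followed by a PAM matching
#' `pam_pattern` (PAM immediately 3' of the protospacer on the protospacer
#' strand). The on-target locus itself appears as a 0-mismatch candidate and
#' is flagged.
#'
#' @param genome named character vector of chromosome sequences.
#' @param gRNAs list of [target_site()] objects, or a data.frame with columns
#'   `site_id` and `protospacer`.
#' @param max_mm mismatch budget, 0..6.
#' @param pam_pattern 3-symbol IUPAC pattern (default `"NGG"`; use `"NGN"`
#'   for relaxed NG PAMs).
#' @return data.frame of candidates sorted by (chrom, start, strand):
#'   `chrom`, `start`, `end` (0-based half-open protospacer interval),
#'   `strand`, `seq` (protospacer-strand orientation), `mismatch_count`,
#'   `pam`, `source_gRNA`, `is_on_target` (`mismatch_count == 0`).
#' @export
enumerate_sites <- function(genome, gRNAs, max_mm = 3, pam_pattern = "NGG") {
  if (!is.numeric(max_mm) || max_mm < 0 || max_mm > 6)
    stop("max_mm must lie in 0..6")
  if (all(nchar(genome) < 23))
    stop("genome has no chromosome of at least 23 nt")
  if (is.data.frame(gRNAs)) {
    grna_df <- gRNAs[, c("site_id", "protospacer")]
  } else {
    if (inherits(gRNAs, "TargetSite")) gRNAs <- list(gRNAs)
    grna_df <- data.frame(
      site_id = vapply(gRNAs, function(s) s$site_id, character(1)),
      protospacer = vapply(gRNAs, function(s) s$protospacer, character(1)),
      stringsAsFactors = FALSE)
  }
  out <- list()
  for (gi in seq_len(nrow(grna_df))) {
    proto <- toupper(grna_df$protospacer[gi])
    for (ch in names(genome)) {
      seq_f <- toupper(genome[[ch]])
      L <- nchar(seq_f)
      fwd <- scan_strand(seq_f, proto, max_mm, pam_pattern)
      if (!is.null(fwd)) {
        fwd$chrom <- ch; fwd$strand <- "+"
        fwd$start <- fwd$offset; fwd$end <- fwd$offset + 20L
        out[[length(out) + 1L]] <- cbind(fwd, source_gRNA = grna_df$site_id[gi])
      }
      rev <- scan_strand(revcomp(seq_f), proto, max_mm, pam_pattern)
      if (!is.null(rev)) {
        rev$chrom <- ch; rev$strand <- "-"
        # offset o on the reverse strand: protospacer occupies forward
        # coordinates [L - o - 20, L - o).
        rev$start <- L - rev$offset - 20L
        rev$end <- L - rev$offset
        out[[length(out) + 1L]] <- cbind(rev, source_gRNA = grna_df$site_id[gi])
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), seq = character(),
                      mismatch_count = integer(), pam = character(),
                      source_gRNA = character(), is_on_target = logical(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[, c("chrom", "start", "end", "strand", "seq", "mismatch_count",
                 "pam", "source_gRNA")]
  res <- unique(res)
  res <- res[order(res$chrom, res$start, res$strand, res$source_gRNA), ]
  rownames(res) <- NULL
  res$is_on_target <- res$mismatch_count == 0L
  res
}

#' Write candidate sites as BED6
#'
#' `name` is `source_gRNA:mismatch_count`, `score` the mismatch count.
#'
#' @param candidates data.frame from [enumerate_sites()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_candidates_bed <- function(candidates, path) {
  bed <- data.frame(
    chrom = candidates$chrom, start = candidates$start, end = candidates$end,
    name = paste0(candidates$source_gRNA, ":", candidates$mismatch_count),
    score = candidates$mismatch_count, strand = candidates$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Attribute SNVs to candidate off-target sites
#'
#' Reports, for every SNV falling inside a candidate protospacer interval,
#' its protospacer position (1 = PAM-distal) and the conversion as seen on
#' the protospacer strand (a genomic G>A under a minus-strand candidate is a
#' protospacer-strand C>T). A result is `consistent` when the
#' protospacer-strand conversion is one a base editor produces (C>T, A>G or
#' C>G).
#'
#' @param snvs data.frame with columns `chrom`, `pos` (1-based), `ref`, `alt`
#'   (single bases), and optionally `sample_id`, `af`.
#' @param candidates data.frame from [enumerate_sites()].
#' @return data.frame with one row per (SNV, overlapping candidate):
#'   SNV fields plus `cand_chrom`, `cand_start`, `cand_end`, `cand_strand`,
#'   `source_gRNA`, `mismatch_count`, `proto_position`, `conversion`
#'   (protospacer strand), `consistent`.
#' @export
attribute_snvs <- function(snvs, candidates) {
  empty <- data.frame(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), sample_id = character(), af = numeric(),
    cand_chrom = character(), cand_start = integer(), cand_end = integer(),
    cand_strand = character(), source_gRNA = character(),
    mismatch_count = integer(), proto_position = integer(),
    conversion = character(), consistent = logical(),
    stringsAsFactors = FALSE)
  if (nrow(snvs) == 0 || nrow(candidates) == 0) return(empty)
  if (!"sample_id" %in% names(snvs)) snvs$sample_id <- NA_character_
  if (!"af" %in% names(snvs)) snvs$af <- NA_real_

  snv_gr <- GenomicRanges::GRanges(
    snvs$chrom, IRanges::IRanges(start = snvs$pos, width = 1))
  cand_gr <- GenomicRanges::GRanges(
    candidates$chrom,
    IRanges::IRanges(start = candidates$start + 1L, end = candidates$end))
  ov <- GenomicRanges::findOverlaps(snv_gr, cand_gr, ignore.strand = TRUE)
  if (length(ov) == 0) return(empty)
  si <- S4Vectors::queryHits(ov); ci <- S4Vectors::subjectHits(ov)

  pos0 <- snvs$pos[si] - 1L
  plus <- candidates$strand[ci] == "+"
  proto_position <- ifelse(plus, pos0 - candidates$start[ci] + 1L,
                           candidates$end[ci] - pos0)
  ref_p <- ifelse(plus, snvs$ref[si], complement_base(snvs$ref[si]))
  alt_p <- ifelse(plus, snvs$alt[si], complement_base(snvs$alt[si]))
  conversion <- paste0(ref_p, ">", alt_p)
  data.frame(
    chrom = snvs$chrom[si], pos = snvs$pos[si], ref = snvs$ref[si],
    alt = snvs$alt[si], sample_id = snvs$sample_id[si], af = snvs$af[si],
    cand_chrom = candidates$chrom[ci], cand_start = candidates$start[ci],
    cand_end = candidates$end[ci], cand_strand = candidates$strand[ci],
    source_gRNA = candidates$source_gRNA[ci],
    mismatch_count = candidates$mismatch_count[ci],
    proto_position = as.integer(proto_position),
    conversion = conversion,
    consistent = conversion %in% c("C>T", "A>G", "C>G"),
    stringsAsFactors = FALSE)
}
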