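OUTCOME_CLASSES <- c("WT", "C_TO_T", "A_TO_G", "SIMULTANEOUS", "C_TO_G",
                     "OTHER_SUB", "INDEL")

# Amplicon-strand columns (1-based) of protospacer positions 1..20, ordered by
# protospacer position.
proto_columns <- function(site) {
  if (site$strand == "+") site$offset + 1:20 else site$offset + 21 - (1:20)
}

# protospacer +/- PAM footprint on the amplicon, 1-based inclusive.
protopam_region <- function(site) {
  if (site$strand == "+") c(site$offset + 1L, site$offset + 23L)
  else c(site$offset - 2L, site$offset + 20L)
}

#' Globally align a read to its amplicon
#'
#' Needleman-Wunsch alignment with affine gaps (match +2, mismatch -1, gap
#' open -6, gap extend -1) via \pkg{Biostrings}. Reads whose alignment
#' identity over the amplicon falls below `min_identity` are flagged as
#' discarded (counted, not errored). Reads of exactly amplicon length with
#' identity above `fast_identity` take a gap-free fast path that skips the
#' dynamic program.
#'
#' @param read DNA string.
#' @param site a [target_site()].
#' @param min_identity identity floor for retaining a read (default 0.6).
#' @param fast_identity identity above which an equal-length read is treated
#'   as gap-free without alignment (default 0.9).
#' @return list of class `read_alignment`: `retained`, `identity`,
#'   `proto_bases` (read bases at protospacer positions 1..20, protospacer
#'   orientation, `"-"` for deletion), `gaps` (data.frame `type`
#'   (`"del"`/`"ins"`), `start`, `end` amplicon coordinates, `length`),
#'   `gap_in_protopam` (any gap overlapping the protospacer+PAM footprint).
#' @export
align_read <- function(read, site, min_identity = 0.6, fast_identity = 0.9) {
  stopifnot(inherits(site, "TargetSite"))
  read <- toupper(read)
  if (nchar(read) == 0) stop("read must be non-empty")
  amp <- site$amplicon
  L <- nchar(amp)

  if (nchar(read) == L) {
    mm <- count_mismatches(read, amp)
    identity <- 1 - mm / L
    if (identity >= fast_identity) {
      return(structure(list(
        retained = identity >= min_identity, identity = identity,
        proto_bases = extract_proto_bases(read, site),
        gaps = empty_gaps(), gap_in_protopam = FALSE),
        class = "read_alignment"))
    }
  }

  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(read), Biostrings::DNAString(amp),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -1, baseOnly = FALSE),
    gapOpening = 6, gapExtension = 1)
  identity <- Biostrings::nmatch(aln) / L
  if (identity < min_identity) {
    return(structure(list(retained = FALSE, identity = identity,
                          proto_bases = rep(NA_character_, 20),
                          gaps = empty_gaps(), gap_in_protopam = FALSE),
                     class = "read_alignment"))
  }

  pat <- chars(as.character(Biostrings::alignedPattern(aln)))
  sub <- chars(as.character(Biostrings::alignedSubject(aln)))
  # Walk alignment columns, tracking the amplicon coordinate.
  amp_to_read <- rep("-", L)
  gaps <- list()
  apos <- 0L
  run_type <- NULL; run_start <- NA_integer_; run_len <- 0L
  flush <- function() {
    if (!is.null(run_type)) {
      gaps[[length(gaps) + 1L]] <<- data.frame(
        type = run_type, start = run_start,
        end = if (run_type == "del") run_start + run_len - 1L else run_start,
        length = run_len, stringsAsFactors = FALSE)
      run_type <<- NULL; run_len <<- 0L
    }
  }
  for (k in seq_along(pat)) {
    if (sub[k] != "-") {
      apos <- apos + 1L
      if (pat[k] == "-") {  # deletion in read
        if (identical(run_type, "del")) run_len <- run_len + 1L
        else { flush(); run_type <- "del"; run_start <- apos; run_len <- 1L }
      } else {
        flush()
        amp_to_read[apos] <- pat[k]
      }
    } else {              # insertion in read, anchored after amplicon pos apos
      if (identical(run_type, "ins")) run_len <- run_len + 1L
      else { flush(); run_type <- "ins"; run_start <- apos; run_len <- 1L }
    }
  }
  flush()
  gaps <- if (length(gaps)) do.call(rbind, gaps) else empty_gaps()

  region <- protopam_region(site)
  gap_in <- FALSE
  if (nrow(gaps) > 0) {
    gap_in <- any(ifelse(gaps$type == "del",
                         gaps$start <= region[2] & gaps$end >= region[1],
                         gaps$start >= region[1] & gaps$start < region[2]))
  }
  cols <- proto_columns(site)
  pb <- amp_to_read[cols]
  if (site$strand == "-") pb <- ifelse(pb == "-", "-", complement_base(pb))
  structure(list(retained = TRUE, identity = identity, proto_bases = pb,
                 gaps = gaps, gap_in_protopam = gap_in),
            class = "read_alignment")
}

empty_gaps <- function() {
  data.frame(type = character(), start = integer(), end = integer(),
             length = integer(), stringsAsFactors = FALSE)
}

# Protospacer-orientation read bases for a gap-free, full-length read.
extract_proto_bases <- function(read, site) {
  cols <- proto_columns(site)
  pb <- chars(read)[cols]
  if (site$strand == "-") pb <- complement_base(pb)
  pb
}

# Shared classification rule over protospacer-orientation bases.
# Returns list(class, tokens) where tokens are "pos:REF>OBS".
classify_bases <- function(ref, obs) {
  diffpos <- which(obs != ref & obs != "-" & !is.na(obs))
  if (length(diffpos) == 0) return(list(class = "WT", tokens = character(0)))
  r <- ref[diffpos]; o <- obs[diffpos]
  tokens <- paste0(diffpos, ":", r, ">", o)
  ct <- any(r == "C" & o == "T")
  ag <- any(r == "A" & o == "G")
  cg <- any(r == "C" & o == "G")
  cls <- if (ct && ag) "SIMULTANEOUS"
         else if (ct) "C_TO_T"
         else if (ag) "A_TO_G"
         else if (cg) "C_TO_G"
         else "OTHER_SUB"
  list(class = cls, tokens = tokens)
}

#' Classify one aligned read into a base-editing outcome
#'
#' A read is `INDEL` when any alignment gap overlaps the protospacer+PAM
#' footprint. Otherwise substitutions are collected over protospacer positions
#' 1..20 (protospacer-strand orientation) and the class assigned by
#' precedence `SIMULTANEOUS` (at least one C>T and one A>G) > `C_TO_T` >
#' `A_TO_G` > `C_TO_G` > `OTHER_SUB` > `WT`.
#'
#' @param alignment a retained alignment from [align_read()].
#' @param site the [target_site()] the read was aligned to.
#' @param read_id optional identifier carried through.
#' @return list of class `ReadOutcome`: `read_id`, `class`,
#'   `edited_positions` (data.frame `position`, `conversion`), `allele`
#'   (protospacer-region sequence as read, protospacer orientation).
#' @export
classify_read <- function(alignment, site, read_id = NA_character_) {
  stopifnot(inherits(alignment, "read_alignment"))
  if (!alignment$retained)
    stop("classify_read() requires an alignment retained by align_read()")
  allele <- paste(alignment$proto_bases, collapse = "")
  if (alignment$gap_in_protopam) {
    return(structure(list(read_id = read_id, class = "INDEL",
                          edited_positions = data.frame(
                            position = integer(), conversion = character(),
                            stringsAsFactors = FALSE),
                          allele = allele),
                     class = "ReadOutcome"))
  }
  cl <- classify_bases(chars(site$protospacer), alignment$proto_bases)
  ep <- if (length(cl$tokens)) {
    parts <- strsplit(cl$tokens, ":", fixed = TRUE)
    data.frame(position = as.integer(vapply(parts, `[`, "", 1)),
               conversion = vapply(parts, `[`, "", 2),
               stringsAsFactors = FALSE)
  } else data.frame(position = integer(), conversion = character(),
                    stringsAsFactors = FALSE)
  structure(list(read_id = read_id, class = cl$class, edited_positions = ep,
                 allele = allele),
            class = "ReadOutcome")
}

#' Classify a set of reads against a target site
#'
#' Vectorized driver for [align_read()] + [classify_read()]: full-length
#' high-identity reads are classified by direct positional comparison;
#' length-changed or low-identity reads fall back to the affine-gap aligner.
#' Results are identical to classifying each read individually.
#'
#' @param reads named character vector of read sequences.
#' @param site a [target_site()].
#' @param min_identity identity floor below which reads are discarded.
#' @return data.frame with one row per input read: `read_id`, `status`
#'   (`"retained"`/`"discarded"`), `class` (NA when discarded), `edits`
#'   (";"-joined `pos:REF>OBS` tokens over protospacer positions), `allele`.
#' @export
analyze_reads <- function(reads, site, min_identity = 0.6) {
  stopifnot(inherits(site, "TargetSite"))
  n <- length(reads)
  if (n == 0) stop("no reads supplied")
  reads <- toupper(reads)
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_len(n))
  amp <- site$amplicon
  L <- nchar(amp)
  ref <- chars(site$protospacer)

  status <- character(n); cls <- rep(NA_character_, n)
  edits <- rep(NA_character_, n); allele <- rep(NA_character_, n)

  fast <- which(nchar(reads) == L)
  slow <- setdiff(seq_len(n), fast)

  if (length(fast) > 0) {
    amp_chars <- chars(amp)
    chunk <- 20000L
    for (s0 in seq(1L, length(fast), by = chunk)) {
      sel <- fast[s0:min(s0 + chunk - 1L, length(fast))]
      M <- matrix(unlist(strsplit(reads[sel], "", fixed = TRUE),
                         use.names = FALSE), ncol = L, byrow = TRUE)
      mm <- rowSums(M != matrix(amp_chars, nrow(M), L, byrow = TRUE))
      identity <- 1 - mm / L
      # Equal-length but heavily diverged reads may still align with gaps;
      # hand them to the full aligner.
      direct <- identity >= 0.9
      for (i in which(!direct)) slow <- c(slow, sel[i])
      keep <- sel[direct]
      if (length(keep) == 0) next
      Mk <- M[direct, , drop = FALSE]
      cols <- proto_columns(site)
      PB <- Mk[, cols, drop = FALSE]
      if (site$strand == "-")
        PB <- matrix(complement_base(PB), nrow = nrow(PB))
      id_keep <- identity[direct]
      for (r in seq_along(keep)) {
        i <- keep[r]
        if (id_keep[r] < min_identity) { status[i] <- "discarded"; next }
        cl <- classify_bases(ref, PB[r, ])
        status[i] <- "retained"
        cls[i] <- cl$class
        edits[i] <- paste(cl$tokens, collapse = ";")
        allele[i] <- paste(PB[r, ], collapse = "")
      }
    }
  }

  for (i in slow) {
    a <- align_read(reads[i], site, min_identity = min_identity)
    if (!a$retained) { status[i] <- "discarded"; next }
    oc <- classify_read(a, site, read_id = ids[i])
    status[i] <- "retained"
    cls[i] <- oc$class
    edits[i] <- if (nrow(oc$edited_positions))
      paste(oc$edited_positions$position, ":",
            oc$edited_positions$conversion, sep = "", collapse = ";") else ""
    allele[i] <- oc$allele
  }

  data.frame(read_id = ids, status = status, class = cls, edits = edits,
             allele = allele, stringsAsFactors = FALSE)
}
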