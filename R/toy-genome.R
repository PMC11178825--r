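#' Generate a deterministic random toy genome
#'
#' Draws a uniform-composition random genome with named chromosomes. Identical
#' seeds reproduce identical sequences byte for byte.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length length of each chromosome in bases (>= 1000).
#' @param seed integer seed.
#' @return a named character vector of chromosome sequences (use
#'   [write_genome_fasta()] to serialize).
#' @export
#' @examples
#' g <- make_toy_genome(2, 1000, seed = 7)
#' nchar(g)
make_toy_genome <- function(n_chrom, chrom_length, seed) {
  if (!is_count(n_chrom, 1)) stop("n_chrom must be a positive integer")
  if (!is_count(chrom_length, 1000)) stop("chrom_length must be >= 1000")
  with_rng(seed, {
    g <- vapply(seq_len(n_chrom), function(i)
      paste(sample(DNA_BASES, chrom_length, replace = TRUE), collapse = ""),
      character(1))
    names(g) <- paste0("chr", seq_len(n_chrom))
    g
  })
}

#' Write / read a genome FASTA
#'
#' @param genome named character vector of chromosome sequences.
#' @param path FASTA path.
#' @return `write_genome_fasta` returns `path` invisibly; `read_genome_fasta`
#'   returns a named character vector.
#' @export
write_genome_fasta <- function(genome, path) {
  dna <- Biostrings::DNAStringSet(unname(genome))
  names(dna) <- names(genome)
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  setNames(as.character(dna), sub("\\s.*$", "", names(dna)))
}

#' Plant candidate protospacer sites into a genome
#'
#' Overwrites chosen loci with sequences at an exact Hamming distance from a
#' gRNA protospacer, each followed by a PAM matching `pam_pattern`
#' (minus-strand placements are written as the reverse complement). Mismatch
#' positions and substituted bases are drawn from the seed; every planted
#' locus is re-scanned afterwards to confirm its stated mismatch count and
#' that no extra exact protospacer match was created.
#'
#' @param genome named character vector (e.g. from [make_toy_genome()]).
#' @param protospacer 20-nt gRNA protospacer.
#' @param placements data.frame with columns `chrom`, `offset` (0-based start
#'   of the 23-nt protospacer+PAM block on the forward strand), `strand`
#'   (`"+"`/`"-"`), `n_mismatches` (0..6). Placements must not overlap and
#'   must fit inside their chromosome.
#' @param pam_pattern 3-symbol IUPAC PAM pattern.
#' @param seed integer seed.
#' @return list with `genome` (mutated genome) and `registry`, a data.frame
#'   of planted sites: `chrom`, `start`/`end` (0-based half-open protospacer
#'   coordinates), `strand`, `n_mismatches`, `planted_seq`
#'   (protospacer-strand orientation), `pam`.
#' @export
plant_candidate_sites <- function(genome, protospacer, placements,
                                  pam_pattern = "NGG", seed = 1) {
  protospacer <- toupper(protospacer)
  if (nchar(protospacer) != 20) stop("protospacer must be 20 nt")
  req <- c("chrom", "offset", "strand", "n_mismatches")
  if (!all(req %in% names(placements)))
    stop("placements needs columns: ", paste(req, collapse = ", "))
  if (any(placements$n_mismatches < 0 | placements$n_mismatches > 6))
    stop("n_mismatches must lie in 0..6")
  if (!all(placements$chrom %in% names(genome)))
    stop("placement chromosome not in genome")

  # Bounds and overlap checks on the 23-nt occupied blocks.
  for (i in seq_len(nrow(placements))) {
    L <- nchar(genome[[placements$chrom[i]]])
    if (placements$offset[i] < 0 || placements$offset[i] + 23 > L)
      stop("placement ", i, " exceeds chromosome bounds")
  }
  for (ch in unique(placements$chrom)) {
    p <- placements[placements$chrom == ch, , drop = FALSE]
    if (nrow(p) > 1) {
      o <- p$offset[order(p$offset)]
      if (any(diff(o) < 23)) stop("overlapping placements on ", ch)
    }
  }

  proto <- chars(protospacer)
  with_rng(seed, {
    registry <- NULL
    for (i in seq_len(nrow(placements))) {
      nm <- placements$n_mismatches[i]
      seq_p <- proto
      if (nm > 0) {
        pos <- sample.int(20L, nm)
        seq_p[pos] <- random_bases(nm, not = seq_p[pos])
      }
      pam <- realize_iupac(pam_pattern)
      block <- paste0(paste(seq_p, collapse = ""), pam)
      strand <- placements$strand[i]
      if (strand == "-") block <- revcomp(block)
      ch <- placements$chrom[i]
      off <- placements$offset[i]
      g <- genome[[ch]]
      genome[[ch]] <- paste0(substr(g, 1, off), block,
                             substr(g, off + 24, nchar(g)))
      # Protospacer-only coordinates (PAM excluded), 0-based half-open.
      if (strand == "+") { ps <- off; pe <- off + 20 }
      else { ps <- off + 3; pe <- off + 23 }
      registry <- rbind(registry, data.frame(
        chrom = ch, start = ps, end = pe, strand = strand,
        n_mismatches = nm, planted_seq = paste(seq_p, collapse = ""),
        pam = pam, stringsAsFactors = FALSE))
    }

    # Post-hoc verification: each planted locus reads back at its stated
    # mismatch count, and mismatched planting created no new exact match.
    for (i in seq_len(nrow(registry))) {
      r <- registry[i, ]
      obs <- substr(genome[[r$chrom]], r$start + 1, r$end)
      if (r$strand == "-") obs <- revcomp(obs)
      if (count_mismatches(obs, protospacer) != r$n_mismatches)
        stop("internal error: planted site ", i, " failed verification")
    }
    n_exact_expected <- sum(registry$n_mismatches == 0)
    n_exact <- sum(vapply(genome, function(g) {
      length(which(gregexpr(protospacer, g, fixed = TRUE)[[1]] > 0)) +
        length(which(gregexpr(revcomp(protospacer), g, fixed = TRUE)[[1]] > 0))
    }, numeric(1)))
    if (n_exact < n_exact_expected)
      stop("internal error: exact planted sites not recoverable")

    list(genome = genome, registry = registry)
  })
}
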