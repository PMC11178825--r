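#' Simulate amplicon reads from a target site and an editing profile
#'
#' Generates single-end, pre-merged amplicon reads carrying base-editing
#' outcomes drawn from an [editing_profile()]: per-position conversions at
#' protospacer positions whose reference base admits them, small indels
#' (1-5 bp, uniform length, anchored uniformly inside the protospacer) at
#' `indel_rate` per read, and uniform substitution sequencing errors applied
#' last. Under `"linked"` co-occurrence a single uniform draw per read is
#' compared against every position's probability, so all window conversions
#' activate jointly while per-position marginal rates stay exact.
#'
#' Truth labels record the editing outcome of each read (before sequencing
#' error), so estimator accuracy can be measured against known rates.
#'
#' @param site a [target_site()].
#' @param profile an [editing_profile()]. A positive conversion probability at
#'   a position whose protospacer base cannot undergo that conversion is an
#'   error.
#' @param n_reads number of reads (>= 1).
#' @param seed integer seed.
#' @return a list with `reads` (named character vector of read sequences),
#'   `truth` (list: `per_read` data.frame with `read_id`, `class`, `edits`
#'   (";"-separated `pos:conversion` tokens), `has_indel`; `rates` the
#'   generating per-position probabilities; `site_id`; `seed`).
#' @export
#' @examples
#' site <- make_target_site(seed = 1, amplicon_length = 80,
#'                          protospacer = "GACTGCATCAGATCAGGACT")
#' prof <- editing_profile(c_to_t = c(`6` = 0.5))
#' sim <- simulate_amplicon_reads(site, prof, n_reads = 100, seed = 2)
#' table(sim$truth$per_read$class)
simulate_amplicon_reads <- function(site, profile, n_reads, seed) {
  stopifnot(inherits(site, "TargetSite"), inherits(profile, "EditingProfile"))
  if (!is_count(n_reads, min = 1)) stop("n_reads must be a positive integer")
  proto <- chars(site$protospacer)

  # Reject probabilities assigned to positions whose base cannot convert.
  check_base <- function(v, base, what) {
    bad <- which(v > 0 & proto != base)
    if (length(bad) > 0)
      stop(what, " probability at position(s) ", paste(bad, collapse = ","),
           " but protospacer base there is ",
           paste(proto[bad], collapse = ","), ", not ", base)
  }
  check_base(profile$c_to_t, "C", "c_to_t")
  check_base(profile$c_to_g, "C", "c_to_g")
  check_base(profile$a_to_g, "A", "a_to_g")

  amp <- chars(site$amplicon)
  L <- length(amp)
  # Amplicon column and strand-resolved substitution bases for each
  # protospacer position (position 1 = PAM-distal).
  if (site$strand == "+") {
    amp_col <- site$offset + 1:20
    res <- function(b) b
  } else {
    amp_col <- site$offset + 21 - (1:20)
    res <- function(b) complement_base(b)
  }

  with_rng(seed, {
    out_reads <- character(n_reads)
    out_class <- character(n_reads)
    out_edits <- character(n_reads)
    out_indel <- logical(n_reads)
    chunk <- 20000L
    starts <- seq(1L, n_reads, by = chunk)
    for (s0 in starts) {
      idx <- s0:min(s0 + chunk - 1L, n_reads)
      n <- length(idx)
      M <- matrix(rep(amp, each = n), nrow = n)
      edits <- vector("list", n)
      ct_any <- logical(n); ag_any <- logical(n); cg_any <- logical(n)

      u_link <- if (profile$cooccurrence == "linked") runif(n) else NULL
      for (p in 1:20) {
        pct <- profile$c_to_t[p]; pcg <- profile$c_to_g[p]
        pag <- profile$a_to_g[p]
        if (pct + pcg + pag == 0) next
        u <- if (is.null(u_link)) runif(n) else u_link
        col <- amp_col[p]
        if (proto[p] == "C") {
          to_t <- u < pct
          to_g <- !to_t & u < pct + pcg
          M[to_t, col] <- res("T")
          M[to_g, col] <- res("G")
          ct_any <- ct_any | to_t
          cg_any <- cg_any | to_g
          for (i in which(to_t)) edits[[i]] <- c(edits[[i]], paste0(p, ":C>T"))
          for (i in which(to_g)) edits[[i]] <- c(edits[[i]], paste0(p, ":C>G"))
        } else if (proto[p] == "A") {
          to_g <- u < pag
          M[to_g, col] <- res("G")
          ag_any <- ag_any | to_g
          for (i in which(to_g)) edits[[i]] <- c(edits[[i]], paste0(p, ":A>G"))
        }
      }

      has_indel <- runif(n) < profile$indel_rate

      # Uniform sequencing errors for indel-free reads, in matrix form.
      plain <- which(!has_indel)
      if (length(plain) > 0 && profile$seq_error_rate > 0) {
        sub <- M[plain, , drop = FALSE]
        hit <- which(runif(length(sub)) < profile$seq_error_rate)
        if (length(hit) > 0) sub[hit] <- random_bases(length(hit), sub[hit])
        M[plain, ] <- sub
      }
      reads <- apply(M, 1, paste, collapse = "")

      # Indels: 1-5 bp, deletion or insertion, anchored inside the protospacer.
      for (i in which(has_indel)) {
        len <- sample.int(5L, 1)
        anchor <- sample(range(amp_col)[1]:range(amp_col)[2], 1)
        is_del <- runif(1) < 0.5
        r <- chars(reads[i])
        if (is_del) {
          drop <- anchor:min(anchor + len - 1L, L)
          r <- r[-drop]
        } else {
          r <- append(r, random_bases(len), after = anchor)
        }
        if (profile$seq_error_rate > 0) {
          hit <- which(runif(length(r)) < profile$seq_error_rate)
          if (length(hit) > 0) r[hit] <- random_bases(length(hit), r[hit])
        }
        reads[i] <- paste(r, collapse = "")
      }

      cls <- rep("WT", n)
      cls[cg_any] <- "C_TO_G"
      cls[ag_any] <- "A_TO_G"
      cls[ct_any] <- "C_TO_T"
      cls[ct_any & ag_any] <- "SIMULTANEOUS"
      cls[has_indel] <- "INDEL"

      out_reads[idx] <- reads
      out_class[idx] <- cls
      out_edits[idx] <- vapply(edits, function(e)
        if (is.null(e)) "" else paste(e, collapse = ";"), character(1))
      out_indel[idx] <- has_indel
    }

    ids <- sprintf("%s_read%06d", site$site_id, seq_len(n_reads))
    names(out_reads) <- ids
    rates <- list(c_to_t = profile$c_to_t, a_to_g = profile$a_to_g,
                  c_to_g = profile$c_to_g)
    list(reads = out_reads,
         truth = list(
           per_read = data.frame(read_id = ids, class = out_class,
                                 edits = out_edits, has_indel = out_indel,
                                 stringsAsFactors = FALSE),
           rates = rates, site_id = site$site_id, seed = as.integer(seed)))
  })
}

#' Write reads to FASTQ
#'
#' Writes simulated reads as Phred+33 FASTQ with constant quality Q37 (the
#' simulator has no quality model).
#'
#' @param reads named character vector of read sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(unname(reads))
  names(dna) <- names(reads)
  qual <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    strrep("F", n), character(1)))  # "F" = Q37, Phred+33
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read amplicon reads from FASTQ
#'
#' @param path FASTQ path (plain text or gzip).
#' @return named character vector of read sequences.
#' @export
read_reads_fastq <- function(path) {
  dna <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(dna), names(dna))
}
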