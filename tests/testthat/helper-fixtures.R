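# Shared fixtures built in code. All protospacers are designed so the base
# layout (which positions are C / A) is known to the tests that use them.

# Protospacer with C at 5,6,8,9,12 and A at 4,7,10: editable bases inside and
# outside the 4-8 window.
FIX_PROTO <- "GTGACCACCATCGGTTGGTT"

fix_site <- function(seed = 1, amplicon_length = 120, proto = FIX_PROTO) {
  make_target_site(seed, amplicon_length, "NGG", protospacer = proto)
}

# A site whose protospacer window (4-8) contains no A at all.
FIX_PROTO_NOA <- "GTGCCCTCCGGTCGGTTGGT"

# Manually built window summary in the shape aggregate_positions() returns.
fix_summary <- function(means, conversion = "C>T", n = 5) {
  data.frame(position = 1:20, conversion = conversion,
             mean = means, sem = NA_real_, n = n,
             stringsAsFactors = FALSE)
}

# Independent per-read classification oracle: direct string comparison over
# protospacer positions of a gap-free read (plus-strand sites only).
oracle_classify <- function(read, site) {
  stopifnot(site$strand == "+")
  obs <- substr(read, site$offset + 1, site$offset + 20)
  ref <- strsplit(site$protospacer, "")[[1]]
  oc <- strsplit(obs, "")[[1]]
  d <- which(oc != ref)
  if (length(d) == 0) return("WT")
  ct <- any(ref[d] == "C" & oc[d] == "T")
  ag <- any(ref[d] == "A" & oc[d] == "G")
  cg <- any(ref[d] == "C" & oc[d] == "G")
  if (ct && ag) "SIMULTANEOUS"
  else if (ct) "C_TO_T"
  else if (ag) "A_TO_G"
  else if (cg) "C_TO_G"
  else "OTHER_SUB"
}

# Independent exhaustive off-target scan using Biostrings matchPattern plus a
# regex PAM check; coordinates reported like enumerate_sites().
oracle_scan <- function(genome, proto, max_mm, pam_pattern) {
  pam_re <- paste0("^", gsub("N", "[ACGT]", pam_pattern), "$")
  hits <- list()
  for (ch in names(genome)) {
    seq_f <- genome[[ch]]
    L <- nchar(seq_f)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seq_f else revcomp(seq_f)
      m <- Biostrings::matchPattern(proto, Biostrings::DNAString(s),
                                    max.mismatch = max_mm)
      for (st in Biostrings::start(m)) {
        if (st + 22 > L) next  # no room for PAM
        pam <- substr(s, st + 20, st + 22)
        if (!grepl(pam_re, pam)) next
        mm <- sum(strsplit(substr(s, st, st + 19), "")[[1]] !=
                    strsplit(proto, "")[[1]])
        if (mm > max_mm) next
        if (strand == "+") {
          start0 <- st - 1L
        } else {
          start0 <- L - (st - 1L) - 20L
        }
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = ch, start = start0, strand = strand, mismatch_count = mm,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) return(data.frame(chrom = character(),
                                           start = integer(),
                                           strand = character(),
                                           mismatch_count = integer()))
  out <- unique(do.call(rbind, hits))
  out[order(out$chrom, out$start, out$strand), ]
}
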