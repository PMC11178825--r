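#' Construct a target site
#'
#' A `TargetSite` ties together one amplicon, the 20-nt protospacer it
#' contains, the PAM pattern, and the editing window. Positions are numbered
#' 1 (PAM-distal 5' end) to 20 (PAM-proximal); the PAM sits immediately 3' of
#' position 20 on the protospacer strand.
#'
#' @param site_id character identifier.
#' @param amplicon DNA string containing the protospacer.
#' @param protospacer 20-nt DNA string.
#' @param pam_pattern 3-symbol IUPAC string (e.g. `"NGG"`; relaxed NG PAMs are
#'   written `"NGN"`).
#' @param window inclusive editing-window interval within 1..20 (default
#'   `c(4, 8)`, the TadA-8e window).
#' @return an object of class `TargetSite`.
#' @export
target_site <- function(site_id, amplicon, protospacer, pam_pattern = "NGG",
                        window = c(4L, 8L)) {
  amplicon <- toupper(amplicon)
  protospacer <- toupper(protospacer)
  if (nchar(protospacer) != 20) stop("protospacer must be 20 nt")
  if (nchar(pam_pattern) != 3) stop("pam_pattern must have length 3")
  loc <- locate_protospacer(amplicon, protospacer)
  window <- as.integer(window)
  if (length(window) != 2 || window[1] > window[2] ||
      window[1] < 1 || window[2] > 20)
    stop("window must be an interval within 1..20")
  pam <- amplicon_pam(amplicon, loc$offset, loc$strand)
  if (!is.na(pam) && !pam_match(pam, pam_pattern))
    warning("PAM adjacent to protospacer (", pam, ") does not match pattern ",
            pam_pattern)
  structure(
    list(site_id = as.character(site_id), amplicon = amplicon,
         protospacer = protospacer, pam_pattern = toupper(pam_pattern),
         strand = loc$strand, offset = loc$offset, window = window),
    class = "TargetSite"
  )
}

# Observed 3-nt PAM on the protospacer strand, or NA if truncated by the
# amplicon edge.
amplicon_pam <- function(amplicon, offset, strand) {
  n <- nchar(amplicon)
  if (strand == "+") {
    if (offset + 23 > n) return(NA_character_)
    substr(amplicon, offset + 21, offset + 23)
  } else {
    if (offset - 3 < 0) return(NA_character_)
    revcomp(substr(amplicon, offset - 2, offset))
  }
}

#' @exportS3Method base::print
print.TargetSite <- function(x, ...) {
  cat("TargetSite ", x$site_id, ": ", nchar(x$amplicon), " bp amplicon, ",
      "protospacer ", x$protospacer, " (", x$strand, ", offset ", x$offset,
      "), PAM ", x$pam_pattern, ", window [", x$window[1], ",", x$window[2],
      "]\n", sep = "")
  invisible(x)
}

#' Locate a protospacer on an amplicon
#'
#' Finds the unique occurrence of a 20-nt protospacer on either strand of an
#' amplicon.
#'
#' @param amplicon DNA string, at least 23 nt.
#' @param protospacer 20-nt DNA string.
#' @return list with `offset` (0-based start of the protospacer-matching block
#'   on the amplicon's forward strand) and `strand` (`"+"` or `"-"`).
#' @export
#' @examples
#' locate_protospacer(paste0("AAAA", strrep("ACGT", 5), "AGGTTT"),
#'                    strrep("ACGT", 5))
locate_protospacer <- function(amplicon, protospacer) {
  amplicon <- toupper(amplicon)
  protospacer <- toupper(protospacer)
  if (nchar(amplicon) < 23) stop("amplicon must be at least 23 nt")
  if (nchar(protospacer) != 20) stop("protospacer must be 20 nt")
  fwd <- gregexpr(protospacer, amplicon, fixed = TRUE)[[1]]
  fwd <- fwd[fwd > 0]
  rev <- gregexpr(revcomp(protospacer), amplicon, fixed = TRUE)[[1]]
  rev <- rev[rev > 0]
  n <- length(fwd) + length(rev)
  if (n == 0) stop("protospacer not found on either strand of amplicon")
  if (n > 1) stop("protospacer occurs ", n, " times on amplicon; ambiguous")
  if (length(fwd) == 1) list(offset = fwd - 1L, strand = "+")
  else list(offset = rev - 1L, strand = "-")
}

#' Generate a random target site
#'
#' Draws a random amplicon containing exactly one 20-nt protospacer followed
#' by a PAM matching `pam_pattern`, and records its offset and strand. Used to
#' build synthetic study designs; rerunning with the same seed reproduces the
#' site byte for byte.
#'
#' @param seed integer seed; all randomness derives from it.
#' @param amplicon_length total amplicon length in bases (default 250,
#'   a typical targeted-amplicon insert; minimum 40).
#' @param pam_pattern 3-symbol IUPAC PAM pattern.
#' @param protospacer optional fixed 20-nt protospacer to embed; by default a
#'   random one is drawn.
#' @param site_id identifier (default derived from the seed).
#' @param window editing window passed to [target_site()].
#' @return a `TargetSite`.
#' @export
#' @examples
#' make_target_site(seed = 1)
make_target_site <- function(seed, amplicon_length = 250, pam_pattern = "NGG",
                             protospacer = NULL, site_id = NULL,
                             window = c(4L, 8L)) {
  if (!is_count(amplicon_length, min = 40))
    stop("amplicon_length must be an integer >= 40")
  if (nchar(pam_pattern) != 3) stop("pam_pattern must have length 3")
  if (is.null(site_id)) site_id <- sprintf("site_s%d", as.integer(seed))
  with_rng(seed, {
    for (attempt in 1:100) {
      proto <- if (is.null(protospacer)) {
        paste(sample(DNA_BASES, 20, replace = TRUE), collapse = "")
      } else toupper(protospacer)
      if (nchar(proto) != 20) stop("protospacer must be 20 nt")
      pam <- realize_iupac(pam_pattern)
      block <- paste0(proto, pam)
      flank_total <- amplicon_length - 23L
      left <- if (flank_total > 0) sample.int(flank_total + 1L, 1) - 1L else 0L
      right <- flank_total - left
      amp <- paste0(
        paste(sample(DNA_BASES, left, replace = TRUE), collapse = ""),
        block,
        paste(sample(DNA_BASES, right, replace = TRUE), collapse = "")
      )
      # The protospacer must be unique across both strands for downstream
      # read anchoring; random flanks almost never collide, but verify.
      n_hits <- length(which(gregexpr(proto, amp, fixed = TRUE)[[1]] > 0)) +
        length(which(gregexpr(revcomp(proto), amp, fixed = TRUE)[[1]] > 0))
      if (n_hits == 1) {
        return(target_site(site_id, amp, proto, pam_pattern, window))
      }
    }
    stop("failed to construct a unique protospacer placement")
  })
}

#' Write / read target-site tables
#'
#' Serializes a list of `TargetSite` objects to the package's TSV layout
#' (`site_id`, `amplicon_seq`, `protospacer`, `pam_pattern`, `strand`,
#' `offset` 0-based, `window_start`, `window_end`).
#'
#' @param sites list of `TargetSite` objects.
#' @param path file path.
#' @return `write_sites_tsv` returns `path` invisibly; `read_sites_tsv`
#'   returns a list of `TargetSite` objects.
#' @export
write_sites_tsv <- function(sites, path) {
  if (inherits(sites, "TargetSite")) sites <- list(sites)
  df <- do.call(rbind, lapply(sites, function(s) {
    data.frame(site_id = s$site_id, amplicon_seq = s$amplicon,
               protospacer = s$protospacer, pam_pattern = s$pam_pattern,
               strand = s$strand, offset = s$offset,
               window_start = s$window[1], window_end = s$window[2],
               stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sites_tsv
#' @export
read_sites_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    target_site(df$site_id[i], df$amplicon_seq[i], df$protospacer[i],
                df$pam_pattern[i], c(df$window_start[i], df$window_end[i]))
  })
}
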