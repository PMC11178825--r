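#' Generative editing profile for amplicon read simulation
#'
#' An `EditingProfile` holds the per-position conversion probabilities used by
#' [simulate_amplicon_reads()]: one probability per protospacer position
#' (1 = PAM-distal 5' end, 20 = PAM-proximal) for each conversion type, plus a
#' per-read indel rate and a per-base sequencing-error rate. It is the
#' generative counterpart of the per-position efficiency profile a deaminase
#' leaves in amplicon data.
#'
#' @param c_to_t,a_to_g,c_to_g named numeric vectors of conversion
#'   probabilities; names are protospacer positions in `1:20`. Unnamed
#'   length-20 vectors are taken as positions 1..20. Positions omitted get
#'   probability 0.
#' @param cooccurrence `"independent"` (each position converts independently)
#'   or `"linked"` (a single draw per read jointly activates every conversion
#'   whose probability exceeds it, so high-probability window positions edit
#'   together, reproducing simultaneous C-to-T and A-to-G alleles).
#' @param indel_rate probability that a read carries a small (1-5 bp) indel
#'   anchored in the protospacer.
#' @param seq_error_rate per-base uniform substitution error applied after
#'   editing.
#' @return an object of class `EditingProfile`.
#' @export
#' @examples
#' editing_profile(c_to_t = c(`5` = 0.4, `6` = 0.3), indel_rate = 0.005)
editing_profile <- function(c_to_t = NULL, a_to_g = NULL, c_to_g = NULL,
                            cooccurrence = c("independent", "linked"),
                            indel_rate = 0, seq_error_rate = 0) {
  cooccurrence <- match.arg(cooccurrence)
  norm <- function(v, what) {
    out <- setNames(numeric(20), as.character(1:20))
    if (is.null(v)) return(out)
    if (is.null(names(v))) {
      if (length(v) != 20)
        stop(what, " must be named by position or have length 20")
      names(v) <- as.character(1:20)
    }
    pos <- suppressWarnings(as.integer(names(v)))
    if (anyNA(pos) || any(pos < 1 | pos > 20))
      stop(what, ": positions must lie in 1..20")
    if (any(v < 0 | v > 1)) stop(what, ": probabilities must lie in [0,1]")
    out[as.character(pos)] <- as.numeric(v)
    out
  }
  prof <- structure(
    list(c_to_t = norm(c_to_t, "c_to_t"),
         a_to_g = norm(a_to_g, "a_to_g"),
         c_to_g = norm(c_to_g, "c_to_g"),
         cooccurrence = cooccurrence,
         indel_rate = indel_rate,
         seq_error_rate = seq_error_rate),
    class = "EditingProfile"
  )
  validate_editing_profile(prof)
  prof
}

validate_editing_profile <- function(p) {
  stopifnot(inherits(p, "EditingProfile"))
  for (f in c("indel_rate", "seq_error_rate")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1)
      stop(f, " must be a probability in [0,1]")
  }
  # At a C position both C->T and C->G compete for the same base; their summed
  # probability may not exceed 1.
  tot_c <- p$c_to_t + p$c_to_g
  if (any(tot_c > 1 + 1e-12))
    stop("c_to_t + c_to_g exceeds 1 at position(s) ",
         paste(which(tot_c > 1), collapse = ","))
  if (any(p$a_to_g > 1)) stop("a_to_g probability above 1")
  invisible(p)
}

#' @exportS3Method base::print
print.EditingProfile <- function(x, ...) {
  cat("EditingProfile (", x$cooccurrence, " co-occurrence)\n", sep = "")
  show <- function(v, lab) {
    nz <- v[v > 0]
    if (length(nz))
      cat("  ", lab, ": ", paste0("p", names(nz), "=", signif(nz, 3),
                                  collapse = " "), "\n", sep = "")
  }
  show(x$c_to_t, "C>T")
  show(x$a_to_g, "A>G")
  show(x$c_to_g, "C>G")
  cat("  indel_rate=", x$indel_rate, " seq_error_rate=", x$seq_error_rate,
      "\n", sep = "")
  invisible(x)
}

#' Preset editing profiles
#'
#' Plausible presets for the editor families the package models: a
#' narrow-window cytosine editor (TadA-8e-derived CBE style, window 4-8), a
#' narrow-window adenine editor (ABE8e style), a dual editor with overlapping
#' C-to-T and A-to-G windows, and a broad-window cytosine editor (APOBEC
#' A3A style, window 3-16). Magnitudes are illustrative defaults, not
#' measured values.
#'
#' @param editor one of `"cbe_narrow"`, `"abe"`, `"dual"`, `"cbe_broad"`.
#' @param peak peak per-position conversion probability (default 0.5).
#' @param indel_rate,seq_error_rate passed to [editing_profile()].
#' @return an `EditingProfile`.
#' @export
#' @examples
#' preset_profile("dual")
preset_profile <- function(editor = c("cbe_narrow", "abe", "dual", "cbe_broad"),
                           peak = 0.5, indel_rate = 0.005,
                           seq_error_rate = 0.003) {
  editor <- match.arg(editor)
  narrow <- setNames(peak * c(0.5, 1, 1, 1, 0.5), as.character(4:8))
  broad  <- setNames(peak * c(0.4, rep(1, 12), 0.4), as.character(3:16))
  args <- switch(editor,
    cbe_narrow = list(c_to_t = narrow),
    abe        = list(a_to_g = narrow),
    dual       = list(c_to_t = narrow, a_to_g = narrow,
                      cooccurrence = "linked"),
    cbe_broad  = list(c_to_t = broad)
  )
  do.call(editing_profile,
          c(args, list(indel_rate = indel_rate,
                       seq_error_rate = seq_error_rate)))
}

#' Restrict a profile to the positions a site can edit
#'
#' Zeroes conversion probabilities at protospacer positions whose reference
#' base cannot undergo them, mirroring the biology that a deaminase edits
#' only positions carrying its substrate base (a site with no editable A in
#' the window simply shows no A-to-G editing).
#'
#' @param profile an [editing_profile()].
#' @param site a [target_site()].
#' @return an `EditingProfile` valid for `site`.
#' @export
restrict_profile <- function(profile, site) {
  stopifnot(inherits(profile, "EditingProfile"), inherits(site, "TargetSite"))
  p <- chars(site$protospacer)
  profile$c_to_t[p != "C"] <- 0
  profile$c_to_g[p != "C"] <- 0
  profile$a_to_g[p != "A"] <- 0
  profile
}
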