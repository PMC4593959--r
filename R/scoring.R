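# PrSM-level metrics, PTM localization and decoy-based FDR.

#' Sequence coverage from the largest matching b and y ions
#'
#' For a protein of n residues with largest matching ions b_j and y_k:
#' 100% if j + k >= n, otherwise (j + k) * 100 / n. Pass 0 for an absent
#' series.
#'
#' @param j Largest matching b index (0 if none).
#' @param k Largest matching y index (0 if none).
#' @param n Sequence length (> 0).
#' @return Coverage in percent.
#' @export
sequence_coverage <- function(j, k, n) {
  if (n <= 0) stop("sequence length must be positive")
  if (j + k >= n) 100 else (j + k) * 100 / n
}

#' Peptide bond coverage of matching b/y ions
#'
#' Bond i (between residues i and i+1, i in 1..n-1) is covered iff some
#' matching b_i or y_(n-i) exists; b_i and y_(n-i) cover the same bond.
#'
#' @param ions A data.frame of matching ions with columns `series`
#'   ("b"/"y"; other series are ignored) and `index`.
#' @param n Sequence length (>= 2).
#' @return Percentage of the n-1 bonds covered.
#' @export
bond_coverage <- function(ions, n) {
  if (n < 2) stop("sequence must have at least 2 residues")
  if (nrow(ions) == 0) return(0)
  b <- ions$index[ions$series == "b"]
  y <- n - ions$index[ions$series == "y"]
  bonds <- unique(c(b, y))
  bonds <- bonds[bonds >= 1 & bonds <= n - 1]
  length(bonds) * 100 / (n - 1)
}

#' Percentage of matching product ions (PMP)
#'
#' Matching b/y ions counted once per (series, index) across charge states
#' and neutral losses, as a percentage of the theoretical (series, index)
#' count. PrSMs are conventionally reported only when PMP >= 5.
#'
#' @param matching A data.frame of matching ions (`series`, `index`).
#' @param n_theoretical Theoretical b/y (series, index) count (> 0); for a
#'   proteoform of length n with both series this is 2 * (n - 1).
#' @return PMP in percent.
#' @export
pmp <- function(matching, n_theoretical) {
  if (n_theoretical <= 0) stop("theoretical ion count must be > 0")
  if (nrow(matching) == 0) return(0)
  by <- matching[matching$series %in% c("b", "y"), , drop = FALSE]
  n_match <- nrow(unique(by[, c("series", "index")]))
  n_match * 100 / n_theoretical
}

#' Interpreted peak and abundance percentages
#'
#' The fraction of experimental peaks linked by at least one fished ion,
#' and the fraction of total spectrum abundance those peaks carry.
#'
#' @param matches A list of `envelope_match` objects (all fished ions,
#'   matching or not).
#' @param spec The `centroid_spectrum`.
#' @return A named numeric vector `c(peaks = ..., abundance = ...)`, both
#'   in percent.
#' @export
interpreted_fractions <- function(matches, spec) {
  if (length(spec$mz) == 0) stop("empty spectrum")
  linked <- unique(unlist(lapply(matches, function(m)
    m$exp_idx[!is.na(m$exp_idx)])))
  c(peaks = length(linked) * 100 / length(spec$mz),
    abundance = sum(spec$abundance[linked]) * 100 / sum(spec$abundance))
}

#' PTM localization score
#'
#' Counts the non-redundant matching b/y ions that independently define a
#' PTM's localization: ions that contain the modified site but exclude at
#' least one alternative candidate site (when alternatives exist). An ion
#' observed at several charge states or with several neutral losses is
#' counted once per (series, index).
#'
#' @param matching A data.frame of matching ions (`series`, `index`).
#' @param site The localized (modified) residue index.
#' @param candidate_sites All candidate sites for this PTM (must include
#'   `site`).
#' @param n Sequence length.
#' @return Integer score (>= 0).
#' @export
ptm_score <- function(matching, site, candidate_sites, n) {
  stopifnot(site %in% candidate_sites)
  alternatives <- setdiff(candidate_sites, site)
  by <- unique(matching[matching$series %in% c("b", "y"),
                        c("series", "index"), drop = FALSE])
  if (nrow(by) == 0) return(0L)
  contains <- function(series, index, s) {
    if (series == "b") s <= index else s >= n - index + 1
  }
  disc <- vapply(seq_len(nrow(by)), function(i) {
    ser <- by$series[i]; idx <- by$index[i]
    if (!contains(ser, idx, site)) return(FALSE)
    if (length(alternatives) == 0) return(TRUE)
    any(!vapply(alternatives, contains, logical(1),
                series = ser, index = idx))
  }, logical(1))
  sum(disc)
}

#' Build a decoy protein
#'
#' @param protein_id Accession (prefixed `"DECOY_"` in the result).
#' @param sequence Amino-acid sequence.
#' @param mode `"reverse"` or `"random"` (uniform permutation).
#' @param seed Integer seed for `"random"` mode (same seed, same shuffle).
#' @return A list with `protein_id` and `sequence`.
#' @export
make_decoy <- function(protein_id, sequence, mode = c("reverse", "random"),
                       seed = 1L) {
  mode <- match.arg(mode)
  if (nchar(sequence) == 0) stop("empty sequence")
  chars <- strsplit(sequence, "")[[1]]
  out <- if (mode == "reverse") rev(chars) else {
    withr_seed <- .save_seed()
    on.exit(.restore_seed(withr_seed))
    set.seed(seed)
    sample(chars)
  }
  list(protein_id = paste0("DECOY_", protein_id),
       sequence = paste0(out, collapse = ""))
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", seed, envir = globalenv())
}

#' Filter target matches at a decoy-estimated FDR
#'
#' Scans score cutoffs from strict to loose and keeps the loosest cutoff
#' whose decoy-estimated FDR, `#{decoy >= cutoff} / #{target >= cutoff}`,
#' stays below `alpha`; at a cutoff where the estimate equals `alpha`
#' exactly the stricter cutoff wins (deterministic tie-break). Returns the
#' surviving targets.
#'
#' @param target_scores Numeric scores of target matches.
#' @param decoy_scores Numeric scores of decoy matches (same score scale).
#' @param alpha Accepted FDR (fraction, e.g. 0.01).
#' @return A list with `cutoff` (score threshold, `Inf` if nothing can be
#'   accepted), `accept` (logical over targets), and `n_accepted`.
#' @export
fdr_filter <- function(target_scores, decoy_scores, alpha = 0.01) {
  if (length(target_scores) == 0)
    return(list(cutoff = Inf, accept = logical(0), n_accepted = 0L))
  cuts <- sort(unique(target_scores), decreasing = TRUE)
  pass <- vapply(cuts, function(ct) {
    nt <- sum(target_scores >= ct)
    nd <- sum(decoy_scores >= ct)
    nd == 0 || nd / nt < alpha
  }, logical(1))
  best <- if (any(pass)) min(cuts[pass]) else Inf
  accept <- target_scores >= best
  list(cutoff = best, accept = accept, n_accepted = sum(accept))
}

#' Group PrSMs into unique proteoforms
#'
#' PrSMs are grouped by (sequence, PTM set); within a group only the PrSM
#' with the most matching b/y ions is kept (ties: higher rank score, then
#' lower scan id).
#'
#' @param prsms A data.frame with at least `sequence`, `ptm_string`,
#'   `n_matching`, `rank_score`, `scan_id`.
#' @return The surviving rows, one per unique proteoform.
#' @export
group_proteoforms <- function(prsms) {
  if (nrow(prsms) == 0) return(prsms)
  key <- paste(prsms$sequence, prsms$ptm_string, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(prsms)), key), function(idx) {
    o <- order(-prsms$n_matching[idx], -prsms$rank_score[idx],
               prsms$scan_id[idx])
    idx[o][1]
  }))
  out <- prsms[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}
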