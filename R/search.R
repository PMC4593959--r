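# End-to-end protein-spectrum matching: database generation, fishing,
# overlap resolution, PrSM metrics and FDR filtering.

#' Default search configuration
#'
#' Engine defaults: precursor tolerances 40/15/100 and product tolerances
#' 20/15/50 (IPACO %/IPMD ppm/IPAD points), b/y ions with all five neutral
#' losses available but disabled by default for identification, PMP >= 5,
#' spectrum-level FDR 1% against a random decoy database, and overlap
#' resolution enabled.
#'
#' @param ... Named overrides of any configuration field.
#' @return A `run_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    precursor = search_params(40, 15, 100, scope = "precursor"),
    product = search_params(20, 15, 50, scope = "product"),
    series = c("b", "y"),
    losses = character(0),
    max_product_charge = 15L,
    product_mz_window = c(0, Inf),
    precursor_mz_window = c(600, 2000),
    pmp_min = 5,
    fdr_alpha = 0.01,
    decoy_mode = "random",
    decoy_seed = 7L,
    resolve = TRUE,
    precursor_check = FALSE,
    k_max = 10L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

# data.frame of matching ions (series/index/nl/charge) from a match list
.matching_ions <- function(matches, identification_only = TRUE) {
  rows <- lapply(matches, function(m) {
    if (!identical(m$verdict, "matching")) return(NULL)
    if (identification_only &&
        (!(m$series %in% c("b", "y")) || m$nl != "none")) return(NULL)
    data.frame(series = m$series, index = m$index, nl = m$nl,
               charge = m$charge, label = m$label, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(series = character(0), index = integer(0),
                      nl = character(0), charge = integer(0),
                      label = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Match one proteoform against one spectrum
#'
#' Generates the proteoform's product-ion database, fishes every ion,
#' optionally resolves overlapping isotopic peaks, classifies the matches
#' and computes the PrSM metrics. Identification metrics use plain b/y
#' matching ions, charge-collapsed; interpreted fractions use all fished
#' ions.
#'
#' @param spec A `centroid_spectrum`.
#' @param pf A `proteoform`.
#' @param config A [default_config()] list.
#' @param is_decoy Logical flag carried into the PrSM.
#' @return A `prsm` object: list with `summary` (one-row data.frame),
#'   `matches`, `resolution` (list of `resolution_result` or NULL), and
#'   the inputs.
#' @export
search_spectrum <- function(spec, pf, config = default_config(),
                            is_decoy = FALSE) {
  db <- generate_fragments(pf, series = config$series,
                           losses = config$losses,
                           max_charge = config$max_product_charge,
                           mz_window = config$product_mz_window,
                           ipaco = config$product$ipaco)
  matches <- fish_spectrum(db, spec, config$product)
  resolution <- NULL
  if (config$resolve && length(matches)) {
    r <- resolve_spectrum(matches, spec, config$product)
    matches <- r$matches
    resolution <- r$groups
  }
  n <- nchar(pf$sequence)
  ions <- .matching_ions(matches)
  j <- if (any(ions$series == "b")) max(ions$index[ions$series == "b"]) else 0
  k <- if (any(ions$series == "y")) max(ions$index[ions$series == "y"]) else 0
  n_matching <- if (nrow(ions)) nrow(unique(ions[, c("series", "index")])) else 0L
  bc <- bond_coverage(ions, n)
  interp <- if (length(matches)) interpreted_fractions(matches, spec)
            else c(peaks = 0, abundance = 0)
  summary <- data.frame(
    scan_id = spec$scan_id,
    protein_id = pf$protein_id,
    sequence = pf$sequence,
    ptm_string = proteoform_ptm_string(pf),
    is_decoy = is_decoy,
    n_matching = n_matching,
    rank_score = n_matching + bc / 1e4,
    pmp = pmp(ions, 2 * (n - 1)),
    sequence_coverage = sequence_coverage(j, k, n),
    bond_coverage = bc,
    interpreted_peak_pct = unname(interp["peaks"]),
    interpreted_abundance_pct = unname(interp["abundance"]),
    stringsAsFactors = FALSE)
  structure(list(summary = summary, matches = matches,
                 resolution = resolution, proteoform = pf,
                 spectrum = spec),
            class = "prsm")
}

#' @export
print.prsm <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<prsm> %s vs %s (%s): %d matching b/y ions, ",
                     "PMP %.1f%%, seq cov %.1f%%, bond cov %.1f%%\n"),
              s$scan_id, s$protein_id, s$ptm_string, s$n_matching,
              s$pmp, s$sequence_coverage, s$bond_coverage))
  invisible(x)
}

# does any precursor charge state of pf explain the spectrum's precursor?
.precursor_ok <- function(spec, pf, config) {
  if (is.na(spec$precursor_mz)) return(TRUE)
  db <- precursor_envelopes(pf, mz_window = config$precursor_mz_window,
                            ipaco = config$precursor$ipaco)
  if (!is.na(spec$precursor_charge))
    db <- db[db$charge == spec$precursor_charge, , drop = FALSE]
  for (i in seq_len(nrow(db))) {
    env <- db$envelope[[i]]
    base_mz <- env$mz[env$base_index]
    if (abs(ipmd(base_mz, spec$precursor_mz)) <= config$precursor$ipmd)
      return(TRUE)
  }
  FALSE
}

#' Search a set of spectra against a proteoform database
#'
#' Runs [search_spectrum()] for every spectrum against every target
#' proteoform (and the corresponding decoy proteoforms), keeps per spectrum
#' the best target and best decoy PrSM passing the PMP threshold, applies
#' the decoy-estimated FDR filter at `config$fdr_alpha`, and groups the
#' accepted PrSMs into unique proteoforms.
#'
#' @param spectra List of `centroid_spectrum` objects.
#' @param proteoforms List of `proteoform` objects (targets).
#' @param config A [default_config()] list.
#' @return A list with `prsms` (accepted target PrSM summaries),
#'   `all_prsms` (every scored candidate incl. decoys), `proteoforms`
#'   (grouped accepted PrSMs) and `cutoff` (FDR score cutoff).
#' @export
run_search <- function(spectra, proteoforms, config = default_config()) {
  decoys <- lapply(proteoforms, function(pf) {
    d <- make_decoy(pf$protein_id, pf$sequence, mode = config$decoy_mode,
                    seed = config$decoy_seed)
    proteoform(d$protein_id, d$sequence)
  })
  score_one <- function(spec, pfs, is_decoy) {
    best <- NULL
    for (pf in pfs) {
      if (config$precursor_check && !.precursor_ok(spec, pf, config)) next
      pr <- search_spectrum(spec, pf, config, is_decoy = is_decoy)
      if (pr$summary$pmp < config$pmp_min) next
      if (is.null(best) || pr$summary$rank_score > best$summary$rank_score)
        best <- pr
    }
    best
  }
  rows <- list()
  for (spec in spectra) {
    bt <- score_one(spec, proteoforms, FALSE)
    bd <- score_one(spec, decoys, TRUE)
    if (!is.null(bt)) rows[[length(rows) + 1]] <- bt$summary
    if (!is.null(bd)) rows[[length(rows) + 1]] <- bd$summary
  }
  all_prsms <- if (length(rows)) do.call(rbind, rows) else
    search_spectrum(centroid_spectrum(1000, 1), proteoforms[[1]],
                    config)$summary[0, ]
  targets <- all_prsms[!all_prsms$is_decoy, , drop = FALSE]
  dec <- all_prsms[all_prsms$is_decoy, , drop = FALSE]
  f <- fdr_filter(targets$rank_score, dec$rank_score, config$fdr_alpha)
  accepted <- targets[f$accept, , drop = FALSE]
  rownames(accepted) <- NULL
  list(prsms = accepted, all_prsms = all_prsms,
       proteoforms = group_proteoforms(accepted), cutoff = f$cutoff)
}
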