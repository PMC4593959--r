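# Partitioning of shared overlapping-isotopic-peak abundance among the
# envelopes that claim it.
#
# Given an OIP shared by n product ions, the ideal experimental abundance
# of the peak in ion i is
#     DEA_i = TA_i * EA_r / TA_r                       (ideal abundance)
# where TA_i is the theoretical relative abundance of the shared peak in
# ion i and (EA_r, TA_r) describe ion i's reference peak. The relative
# deviation of the observed shared abundance EA_OIP from the summed ideal,
#     RD = (EA_OIP - sum DEA) / sum DEA,               (relative deviation)
# then gives the final partitioned abundance
#     final_i = DEA_i * (1 + RD)                       (partition)
# which is algebraically the proportional allocation
# EA_OIP * DEA_i / sum DEA. RD is carried at full precision throughout;
# only reports round it. Each group is resolved independently with 2n + 1
# arithmetic operations.

#' Ideal experimental abundance of a shared peak in one ion
#'
#' @param ta_i Theoretical relative abundance (percent) of the shared peak
#'   in this ion.
#' @param ea_r Absolute experimental abundance of the ion's reference peak.
#' @param ta_r Theoretical relative abundance (percent) of the reference
#'   peak (> 0).
#' @return The ideal absolute abundance `ta_i * ea_r / ta_r` (vectorized).
#' @examples
#' ideal_abundance(23.01, 128926.921875, 63.64)  # 46615.469396
#' @export
ideal_abundance <- function(ta_i, ea_r, ta_r) {
  if (any(ta_r <= 0)) stop("reference theoretical abundance must be > 0")
  ta_i * ea_r / ta_r
}

#' Relative deviation of observed vs summed ideal abundance
#'
#' @param ea_oip Observed absolute abundance of the shared peak.
#' @param deas Ideal abundances of all claimants (from
#'   [ideal_abundance()]).
#' @return `(ea_oip - sum(deas)) / sum(deas)`, full precision.
#' @export
relative_deviation <- function(ea_oip, deas) {
  s <- sum(deas)
  if (s <= 0) stop("summed ideal abundance must be > 0")
  (ea_oip - s) / s
}

#' Partition a shared peak's abundance among its claimant ions
#'
#' Applies the ideal-abundance / relative-deviation / partition pipeline to
#' one OIP group at full precision. With a single claimant the full
#' observed abundance is assigned to it.
#'
#' @param group An `oip_group` (see [find_oips()]), or any list with
#'   `ea_oip` and a `claimants` data.frame carrying `ta_i`, `ea_r`, `ta_r`
#'   (and optionally `label`, `degenerate`).
#' @return A `resolution_result`: list with `ea_oip`, `rd`, and a
#'   data.frame `claimants` gaining columns `dea` and `final`. Errors if
#'   any claimant has a degenerate reference.
#' @export
partition_oip <- function(group) {
  cl <- group$claimants
  if (nrow(cl) < 1) stop("group has no claimants")
  if (!is.null(cl$degenerate) && any(cl$degenerate))
    stop("claimant with degenerate reference; group cannot be partitioned")
  cl$dea <- ideal_abundance(cl$ta_i, cl$ea_r, cl$ta_r)
  rd <- relative_deviation(group$ea_oip, cl$dea)
  cl$final <- cl$dea * (1 + rd)
  structure(list(exp_idx = group$exp_idx, exp_mz = group$exp_mz,
                 ea_oip = group$ea_oip, rd = rd, claimants = cl),
            class = "resolution_result")
}

#' @export
print.resolution_result <- function(x, ...) {
  cat(sprintf("<resolution_result> OIP m/z %.6f, EA = %.6f, RD = %.2f\n",
              x$exp_mz, x$ea_oip, x$rd))
  print(x$claimants)
  invisible(x)
}

#' Resolve every overlapping isotopic peak in a spectrum's matches
#'
#' Orchestrates one resolution pass: detect OIPs, re-select every match's
#' reference peak excluding OIPs, compute provisional relative abundances,
#' partition each group whose shared peak has a provisional IPAD >= 0 for
#' at least one claimant (the shared peak carries surplus abundance),
#' install the partitioned abundances, recompute relative abundances and
#' IPADs, and re-classify. The set of fished ions is never changed --
#' only verdicts and abundances.
#'
#' @param matches Named list of `envelope_match` objects from
#'   [fish_spectrum()].
#' @param spec The `centroid_spectrum` they were fished from.
#' @param params A [search_params()] object.
#' @param gate_nonneg If TRUE (default), only groups whose shared peak has
#'   provisional IPAD >= 0 for at least one claimant are partitioned;
#'   groups failing the gate are left untouched.
#' @return A list with `matches` (updated), `groups` (list of
#'   `resolution_result`), and `skipped` (groups left unpartitioned, with
#'   a reason).
#' @export
resolve_spectrum <- function(matches, spec, params, gate_nonneg = TRUE) {
  groups <- find_oips(matches, spec)
  oip_peaks <- vapply(groups, `[[`, 0L, "exp_idx")
  # re-anchor every match's reference away from shared peaks
  for (lab in names(matches)) {
    m <- matches[[lab]]
    linked <- which(!is.na(m$exp_idx))
    clean <- linked[!(m$exp_idx[linked] %in% oip_peaks)]
    m$reference_degenerate <- length(clean) == 0
    m$reference_index <- select_reference(m, oip_peaks)
    matches[[lab]] <- .update_relatives(m)
  }
  # groups carry reference data captured after re-anchoring
  groups <- find_oips(matches, spec)
  resolved <- list()
  skipped <- list()
  for (g in groups) {
    if (any(g$claimants$degenerate)) {
      skipped[[length(skipped) + 1]] <- list(group = g,
                                             reason = "degenerate reference")
      next
    }
    if (gate_nonneg) {
      prov_ipad <- vapply(seq_len(nrow(g$claimants)), function(k) {
        m <- matches[[g$claimants$label[k]]]
        m$ipad[g$claimants$theo_peak[k]]
      }, numeric(1))
      if (!any(prov_ipad >= 0)) {
        skipped[[length(skipped) + 1]] <- list(group = g,
                                               reason = "IPAD gate")
        next
      }
    }
    res <- partition_oip(g)
    for (k in seq_len(nrow(res$claimants))) {
      lab <- res$claimants$label[k]
      tp <- res$claimants$theo_peak[k]
      matches[[lab]]$exp_abund[tp] <- res$claimants$final[k]
    }
    resolved[[length(resolved) + 1]] <- res
  }
  for (lab in names(matches)) {
    matches[[lab]] <- .update_relatives(matches[[lab]])
    matches[[lab]]$verdict <- classify_match(matches[[lab]], params)
  }
  list(matches = matches, groups = resolved, skipped = skipped)
}

#' Resolution report
#'
#' One row per claimant per resolved group, mirroring the worked-table
#' dialect: absolute abundances to 6 decimals, relative values to 2, RD to
#' 2, IPADs as integers.
#'
#' @param results A list of `resolution_result` objects (e.g.
#'   `resolve_spectrum()$groups`), each optionally carrying
#'   `ipad_before`/`ipad_after` columns in `claimants`.
#' @return A data.frame with columns `group`, `exp_mz`, `ea_oip`, `ion`,
#'   `ta_i`, `ea_r`, `ta_r`, `dea`, `final`, `rd`, and when available
#'   `ipad_before`, `ipad_after`.
#' @export
resolution_report <- function(results) {
  if (length(results) == 0)
    return(data.frame(group = integer(0), exp_mz = numeric(0),
                      ea_oip = numeric(0), ion = character(0),
                      ta_i = numeric(0), ea_r = numeric(0),
                      ta_r = numeric(0), dea = numeric(0),
                      final = numeric(0), rd = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(seq_along(results), function(gi) {
    r <- results[[gi]]
    cl <- r$claimants
    df <- data.frame(group = gi, exp_mz = round(r$exp_mz, 6),
                     ea_oip = round(r$ea_oip, 6), ion = cl$label,
                     ta_i = round(cl$ta_i, 2), ea_r = round(cl$ea_r, 6),
                     ta_r = round(cl$ta_r, 2), dea = round(cl$dea, 6),
                     final = round(cl$final, 6), rd = round(r$rd, 2),
                     stringsAsFactors = FALSE)
    if (!is.null(cl$ipad_before)) df$ipad_before <- as.integer(round(cl$ipad_before))
    if (!is.null(cl$ipad_after)) df$ipad_after <- as.integer(round(cl$ipad_after))
    df
  }))
  rownames(out) <- NULL
  out
}

#' Resolve the overlapping peaks of a tabular match report
#'
#' Works directly on the documented match-report table (see
#' [match_report()]): rows sharing an experimental m/z across two or more
#' ions are OIP groups; each ion's reference is its highest-theoretical-
#' abundance non-overlapping linked row. Every gated group is partitioned
#' and the report's abundances, relative abundances and IPADs are updated.
#' This is the entry point used by the command-line `resolve` subcommand.
#'
#' @param report A data.frame in match-report column order (`ion`,
#'   `theo_mz`, `theo_rel`, `exp_mz`, `exp_abund`, ...).
#' @param params A [search_params()] object used to refresh each ion's
#'   verdict over the rows present in the report.
#' @param gate_nonneg Partition only groups with provisional IPAD >= 0 for
#'   at least one claimant (default TRUE).
#' @return A list with `report` (updated data.frame, IPMD recomputed,
#'   IPAD/exp_rel/verdict refreshed) and `resolution` (the
#'   [resolution_report()] of the partitioned groups, with
#'   `ipad_before`/`ipad_after`).
#' @export
resolve_match_report <- function(report, params = search_params(20, 15, 50),
                                 gate_nonneg = TRUE) {
  need <- c("ion", "theo_mz", "theo_rel", "exp_mz", "exp_abund")
  if (!all(need %in% names(report)))
    stop("report lacks required columns: ",
         paste(setdiff(need, names(report)), collapse = ", "))
  rep <- report
  key <- sprintf("%.6f", rep$exp_mz)
  n_ions <- tapply(rep$ion, key, function(x) length(unique(x)))
  oip_keys <- names(n_ions)[n_ions >= 2]
  rep$is_oip <- key %in% oip_keys
  # reference per ion: non-OIP row with max theo_rel (ties: lower theo m/z)
  ref_row <- integer(0)
  for (lab in unique(rep$ion)) {
    rows <- which(rep$ion == lab & !rep$is_oip)
    if (length(rows) == 0)
      stop("ion ", lab, " has no clean reference peak in the report")
    ref_row[lab] <- rows[order(-rep$theo_rel[rows], rep$theo_mz[rows])][1]
  }
  ea_r <- rep$exp_abund[ref_row[rep$ion]]
  ta_r <- rep$theo_rel[ref_row[rep$ion]]
  ipad_before <- rep$exp_abund * ta_r / ea_r - rep$theo_rel
  results <- list()
  for (k in oip_keys) {
    rows <- which(key == k)
    if (gate_nonneg && !any(ipad_before[rows] >= 0)) next
    group <- list(exp_idx = rows[1], exp_mz = rep$exp_mz[rows[1]],
                  ea_oip = rep$exp_abund[rows[1]],
                  claimants = data.frame(
                    label = rep$ion[rows], theo_peak = rows,
                    ta_i = rep$theo_rel[rows],
                    ea_r = ea_r[rows], ta_r = ta_r[rows],
                    degenerate = FALSE, stringsAsFactors = FALSE))
    res <- partition_oip(group)
    res$claimants$ipad_before <- ipad_before[rows]
    rep$exp_abund[rows] <- res$claimants$final
    res$claimants$ipad_after <-
      res$claimants$final * ta_r[rows] / ea_r[rows] - rep$theo_rel[rows]
    results[[length(results) + 1]] <- res
  }
  ipad_now <- rep$exp_abund * ta_r / ea_r - rep$theo_rel
  ipmd_now <- ipmd(rep$theo_mz, rep$exp_mz)
  rep$exp_rel <- round(rep$exp_abund * ta_r / ea_r, 2)
  rep$ipad <- as.integer(round(ipad_now))
  rep$ipmd <- as.integer(round(ipmd_now))
  rep$exp_abund <- round(rep$exp_abund, 6)
  # verdict over the rows present, on unrounded deviations
  ok <- abs(ipad_now) <= params$ipad & abs(ipmd_now) <= params$ipmd
  ion_ok <- tapply(ok, rep$ion, all)
  rep$verdict <- ifelse(ion_ok[rep$ion], "matching", "non-matching")
  list(report = rep, resolution = resolution_report(results))
}
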