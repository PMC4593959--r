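# Proteoforms, product-ion generation and the theoretical ion database.

#' Create a proteoform
#'
#' A proteoform is a protein sequence plus a concrete set of PTMs, each a
#' site, a name and an elemental-composition delta.
#'
#' @param protein_id Accession string.
#' @param sequence Amino-acid sequence (1-letter codes, 20 standard residues).
#' @param ptms A data.frame with columns `site` (1-based residue index),
#'   `name`, `delta_formula` (additive formula string, e.g. `"C2H2O"` for
#'   acetylation), or NULL for the unmodified form.
#' @return An object of class `proteoform`.
#' @export
proteoform <- function(protein_id, sequence, ptms = NULL) {
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) < 1)
    stop("sequence must be a non-empty string")
  sequence <- toupper(sequence)
  residues <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(residues), names(.RESIDUES))
  if (length(bad))
    stop("non-standard residue(s): ", paste(bad, collapse = ", "))
  if (is.null(ptms))
    ptms <- data.frame(site = integer(0), name = character(0),
                       delta_formula = character(0),
                       stringsAsFactors = FALSE)
  stopifnot(all(c("site", "name", "delta_formula") %in% names(ptms)))
  n <- nchar(sequence)
  if (nrow(ptms)) {
    if (any(ptms$site < 1 | ptms$site > n))
      stop("PTM site out of range")
    if (anyDuplicated(ptms$site))
      stop("more than one PTM on the same site")
    # validate deltas parse
    lapply(ptms$delta_formula, parse_formula)
    ptms <- ptms[order(ptms$site), , drop = FALSE]
    rownames(ptms) <- NULL
  }
  structure(list(protein_id = protein_id, sequence = sequence, ptms = ptms),
            class = "proteoform")
}

#' @export
print.proteoform <- function(x, ...) {
  cat(sprintf("<proteoform> %s (%d aa) %s\n", x$protein_id,
              nchar(x$sequence), proteoform_ptm_string(x)))
  invisible(x)
}

#' Canonical PTM string of a proteoform
#'
#' E.g. `"K37ac,K105ac"`, or `"no PTM"` for the unmodified form.
#' @param pf A `proteoform`.
#' @return A single string.
#' @export
proteoform_ptm_string <- function(pf) {
  if (nrow(pf$ptms) == 0) return("no PTM")
  res <- substring(pf$sequence, pf$ptms$site, pf$ptms$site)
  paste0(res, pf$ptms$site, pf$ptms$name, collapse = ",")
}

#' Neutral elemental composition of a proteoform
#' @param pf A `proteoform`.
#' @return An [elem_comp] (residues + water + PTM deltas).
#' @export
proteoform_composition <- function(pf) {
  comp <- elem_comp(.WATER)
  for (r in strsplit(pf$sequence, "")[[1]])
    comp <- comp_add(comp, residue_composition(r))
  if (nrow(pf$ptms))
    for (f in pf$ptms$delta_formula)
      comp <- comp_add(comp, parse_formula(f))
  comp
}

#' Expand PTM annotations into proteoforms
#'
#' Every annotated site is treated dynamically (may be modified or not), so
#' k annotated sites yield 2^k proteoforms. The unmodified form comes first;
#' combinations are emitted in subset order.
#'
#' @param protein_id Accession string.
#' @param sequence Amino-acid sequence.
#' @param annotations A data.frame with columns `site`, `name`,
#'   `delta_formula` (one row per annotated site), or NULL.
#' @param k_max Maximum number of annotated sites allowed (guards against
#'   combinatorial explosion). Default 10.
#' @return A list of `proteoform` objects, unmodified form first.
#' @examples
#' ann <- data.frame(site = c(37, 105), name = "ac", delta_formula = "C2H2O")
#' # yields 4 proteoforms: no PTM, 37ac, 105ac, 37ac+105ac
#' @export
expand_proteoforms <- function(protein_id, sequence, annotations = NULL,
                               k_max = 10L) {
  if (is.null(annotations) || nrow(annotations) == 0)
    return(list(proteoform(protein_id, sequence)))
  if (anyDuplicated(annotations$site))
    stop("duplicate annotated site")
  k <- nrow(annotations)
  if (k > k_max)
    stop("too many annotated sites (", k, " > k_max = ", k_max, ")")
  out <- vector("list", 2^k)
  for (mask in 0:(2^k - 1)) {
    sel <- bitwAnd(mask, 2^(seq_len(k) - 1)) > 0
    out[[mask + 1]] <- proteoform(protein_id, sequence,
                                  annotations[sel, , drop = FALSE])
  }
  out
}

# ---- ion labels -------------------------------------------------------------

# label token for each neutral loss (written in the field's order)
.NL_LABEL <- c("none" = "", "NH3" = "NH3", "H2O" = "H2O",
               "NH3+H2O" = "H2O-NH3", "2NH3" = "2NH3", "2H2O" = "2H2O")

#' Canonical product-ion label
#'
#' E.g. `"y72-7+"`, `"b111-2H2O-11+"`, `"y142-H2O-NH3-14+"`.
#' @param series One of "a", "b", "y".
#' @param index Cleavage ordinal (1-based).
#' @param nl Neutral loss: "none" or one of [neutral_losses()].
#' @param charge Positive integer.
#' @return A single string.
#' @export
ion_label <- function(series, index, nl = "none", charge = 1L) {
  tok <- .NL_LABEL[[nl]]
  paste0(series, index, if (tok != "") paste0("-", tok), "-", charge, "+")
}

#' Parse a product-ion label
#'
#' Inverse of [ion_label()].
#' @param label A label string such as `"b111-2H2O-11+"`.
#' @return A list with `series`, `index`, `nl`, `charge`.
#' @export
parse_ion_label <- function(label) {
  m <- regmatches(label,
    regexec("^([aby])([0-9]+)(?:-(NH3|H2O|H2O-NH3|2NH3|2H2O))?-([0-9]+)\\+$",
            label))[[1]]
  if (length(m) == 0) stop("malformed ion label: ", label)
  nl_tok <- m[4]
  nl <- if (nl_tok == "") "none" else
    names(.NL_LABEL)[match(nl_tok, .NL_LABEL)]
  list(series = m[2], index = as.integer(m[3]), nl = nl,
       charge = as.integer(m[5]))
}

# ---- fragment compositions --------------------------------------------------

# cumulative element-count matrix: rows = elements, col j = residues 1..j
# (plus PTM deltas on those residues)
.prefix_counts <- function(pf) {
  residues <- strsplit(pf$sequence, "")[[1]]
  n <- length(residues)
  els <- names(.ISOTOPES)
  m <- matrix(0L, nrow = length(els), ncol = n, dimnames = list(els, NULL))
  for (j in seq_len(n)) {
    r <- .RESIDUES[[residues[j]]]
    m[names(r), j] <- r
  }
  if (nrow(pf$ptms)) {
    for (i in seq_len(nrow(pf$ptms))) {
      d <- parse_formula(pf$ptms$delta_formula[i])
      m[names(d), pf$ptms$site[i]] <- m[names(d), pf$ptms$site[i], drop = TRUE] + d
    }
  }
  if (n > 1)
    for (j in 2:n) m[, j] <- m[, j - 1] + m[, j]
  m
}

#' Neutral composition of a backbone fragment
#'
#' b_j is the sum of residue compositions 1..j (with PTM deltas on those
#' residues); y_k adds water to the last k residues; a_j is b_j minus CO.
#' Neutral-loss variants subtract the loss molecule.
#'
#' @param pf A `proteoform`.
#' @param series "a", "b" or "y".
#' @param index Cleavage ordinal, `1 <= index <= nchar(sequence) - 1`.
#' @param nl Neutral loss name or "none".
#' @return An [elem_comp]; errors if a loss would drive a count negative.
#' @export
fragment_composition <- function(pf, series, index, nl = "none") {
  pc <- .prefix_counts(pf)
  n <- ncol(pc)
  if (index < 1 || index > n - 1) stop("fragment index out of range")
  counts <- if (series %in% c("a", "b")) {
    pc[, index]
  } else if (series == "y") {
    v <- pc[, n] - pc[, n - index]
    v[names(.WATER)] <- v[names(.WATER)] + .WATER
    v
  } else stop("unknown series: ", series)
  comp <- elem_comp(counts)
  if (series == "a") comp <- comp_subtract(comp, elem_comp(.CO))
  if (nl != "none") comp <- comp_subtract(comp, elem_comp(.LOSSES[[nl]]))
  comp
}

# which losses a fragment's residue content allows
.eligible_losses <- function(frag_residues, losses) {
  has_h2o <- any(frag_residues %in% .H2O_LOSS_RESIDUES)
  has_nh3 <- any(frag_residues %in% .NH3_LOSS_RESIDUES)
  ok <- vapply(losses, function(nl) {
    needs_h2o <- grepl("H2O", nl)
    needs_nh3 <- grepl("NH3", nl)
    (!needs_h2o || has_h2o) && (!needs_nh3 || has_nh3)
  }, logical(1))
  losses[ok]
}

#' Generate the theoretical product-ion database of a proteoform
#'
#' Emits every requested series/neutral-loss/charge combination whose
#' base-peak (100%) m/z falls inside the window, with its IPACO-truncated
#' exact envelope. Neutral losses are generated only for eligible fragments:
#' H2O-containing losses require at least one of D/E/S/T in the fragment,
#' NH3-containing losses at least one of K/N/Q/R, the combined loss both.
#'
#' @param pf A `proteoform`.
#' @param series Subset of `c("a","b","y")`. Default `c("b","y")`.
#' @param losses Neutral losses to consider (subset of [neutral_losses()]),
#'   or `character(0)` for none, or `"all"`.
#' @param max_charge Highest product charge state to emit (from 1).
#' @param mz_window Length-2 numeric, base-peak m/z window.
#' @param ipaco Envelope abundance cutoff in percent.
#' @return An `ion_db`: a data.frame with columns `label`, `series`,
#'   `index`, `nl`, `charge`, `base_mz`, `mono_mz` and a list column
#'   `envelope` of `theo_envelope` objects.
#' @export
generate_fragments <- function(pf, series = c("b", "y"),
                               losses = character(0),
                               max_charge = 1L,
                               mz_window = c(0, Inf),
                               ipaco = 20) {
  stopifnot(all(series %in% c("a", "b", "y")), max_charge >= 1)
  if (identical(losses, "all")) losses <- neutral_losses()
  stopifnot(all(losses %in% neutral_losses()))
  pc <- .prefix_counts(pf)
  n <- ncol(pc)
  residues <- strsplit(pf$sequence, "")[[1]]
  co <- elem_comp(.CO)
  rows <- list()
  for (idx in seq_len(n - 1)) {
    for (ser in series) {
      frag_res <- if (ser == "y") residues[(n - idx + 1):n]
                  else residues[1:idx]
      counts <- if (ser %in% c("a", "b")) pc[, idx] else {
        v <- pc[, n] - pc[, n - idx]
        v[names(.WATER)] <- v[names(.WATER)] + .WATER
        v
      }
      base_comp <- elem_comp(counts)
      if (ser == "a") base_comp <- comp_subtract(base_comp, co)
      for (nl in c("none", .eligible_losses(frag_res, losses))) {
        comp <- if (nl == "none") base_comp else
          tryCatch(comp_subtract(base_comp, elem_comp(.LOSSES[[nl]])),
                   error = function(e) NULL)
        if (is.null(comp)) next  # loss exceeds fragment content; skip
        agg <- neutral_aggregate(comp)
        for (z in seq_len(max_charge)) {
          env <- envelope_at_charge(agg, charge = z, ipaco = ipaco)
          base_mz <- env$mz[env$base_index]
          if (base_mz < mz_window[1] || base_mz > mz_window[2]) next
          rows[[length(rows) + 1]] <- list(
            label = ion_label(ser, idx, nl, z),
            series = ser, index = idx, nl = nl, charge = z,
            base_mz = base_mz, mono_mz = env$monoisotopic_mz,
            envelope = env)
        }
      }
    }
  }
  .ion_db(rows)
}

.ion_db <- function(rows) {
  if (length(rows) == 0) {
    db <- data.frame(label = character(0), series = character(0),
                     index = integer(0), nl = character(0),
                     charge = integer(0), base_mz = numeric(0),
                     mono_mz = numeric(0), stringsAsFactors = FALSE)
    db$envelope <- list()
  } else {
    db <- data.frame(
      label = vapply(rows, `[[`, "", "label"),
      series = vapply(rows, `[[`, "", "series"),
      index = vapply(rows, `[[`, 0L, "index"),
      nl = vapply(rows, `[[`, "", "nl"),
      charge = vapply(rows, `[[`, 0L, "charge"),
      base_mz = vapply(rows, `[[`, 0, "base_mz"),
      mono_mz = vapply(rows, `[[`, 0, "mono_mz"),
      stringsAsFactors = FALSE)
    db$envelope <- lapply(rows, `[[`, "envelope")
    db <- db[order(db$base_mz), , drop = FALSE]
    rownames(db) <- NULL
  }
  class(db) <- c("ion_db", "data.frame")
  db
}

#' Ions whose base-peak m/z lies in a window
#'
#' @param db An `ion_db` from [generate_fragments()].
#' @param lo,hi Window bounds (inclusive), Th.
#' @return The matching rows of `db`.
#' @export
ions_in_window <- function(db, lo, hi) {
  db[db$base_mz >= lo & db$base_mz <= hi, , drop = FALSE]
}

#' Check b/y complementarity of a proteoform
#'
#' Mass-conservation self test: for every cleavage j, the neutral masses of
#' b_j and y_(n-j) must sum to the proteoform's neutral mass.
#'
#' @param pf A `proteoform`.
#' @param tol Tolerance in Da. Default 1e-6.
#' @return TRUE if every cleavage balances; otherwise FALSE with attribute
#'   `failures` (data.frame of offending cleavages).
#' @export
complementary_mass_check <- function(pf, tol = 1e-6) {
  n <- nchar(pf$sequence)
  total <- monoisotopic_mass(proteoform_composition(pf))
  dev <- vapply(seq_len(n - 1), function(j) {
    b <- monoisotopic_mass(fragment_composition(pf, "b", j))
    y <- monoisotopic_mass(fragment_composition(pf, "y", n - j))
    abs(b + y - total)
  }, numeric(1))
  ok <- all(dev <= tol)
  if (!ok)
    attr(ok, "failures") <- data.frame(j = which(dev > tol),
                                       deviation = dev[dev > tol])
  ok
}

#' Precursor envelopes of a proteoform
#'
#' Same envelope machinery applied to the intact proteoform: one envelope
#' per charge state whose base peak lies in the MS acquisition window.
#'
#' @param pf A `proteoform`.
#' @param mz_window Length-2 numeric MS window, Th.
#' @param ipaco Abundance cutoff in percent.
#' @param max_charge Highest charge state considered. Default 30.
#' @return An `ion_db` with one row per retained charge state (labels
#'   `"M-z+"` with series `"M"`, index 0).
#' @export
precursor_envelopes <- function(pf, mz_window, ipaco = 40, max_charge = 30L) {
  agg <- neutral_aggregate(proteoform_composition(pf))
  rows <- list()
  for (z in seq_len(max_charge)) {
    env <- envelope_at_charge(agg, charge = z, ipaco = ipaco)
    base_mz <- env$mz[env$base_index]
    if (base_mz < mz_window[1] || base_mz > mz_window[2]) next
    rows[[length(rows) + 1]] <- list(
      label = paste0("M-", z, "+"), series = "M", index = 0L, nl = "none",
      charge = z, base_mz = base_mz, mono_mz = env$monoisotopic_mz,
      envelope = env)
  }
  .ion_db(rows)
}
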