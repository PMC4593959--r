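# Independent oracles and fixture builders shared across tests.

# Brute-force isotopologue enumeration: every joint isotope-count state of
# every element, probability from the multinomial law, exact mass as the
# sum of isotope masses; states aggregated by total nucleon offset at the
# very end. Independent of the package's convolution path.
brute_force_envelope <- function(comp) {
  tab <- isotope_table()
  per_element <- lapply(names(comp), function(el) {
    iso <- tab[[el]]
    k <- length(iso$mass)
    n <- comp[[el]]
    # all count vectors (k columns summing to n)
    states <- .compositions(n, k)
    prob <- apply(states, 1, function(ct) stats::dmultinom(ct, prob = iso$abundance))
    mass <- as.numeric(states %*% iso$mass)
    offset <- as.numeric(states %*% round(iso$mass - iso$mass[1]))
    data.frame(prob = prob, mass = mass, offset = offset)
  })
  joint <- Reduce(function(a, b) {
    idx <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
    data.frame(prob = a$prob[idx$i] * b$prob[idx$j],
               mass = a$mass[idx$i] + b$mass[idx$j],
               offset = a$offset[idx$i] + b$offset[idx$j])
  }, per_element)
  agg_p <- tapply(joint$prob, joint$offset, sum)
  agg_m <- tapply(joint$prob * joint$mass, joint$offset, sum) / agg_p
  o <- order(as.numeric(names(agg_p)))
  list(offset = as.numeric(names(agg_p))[o],
       prob = as.numeric(agg_p)[o],
       mass = as.numeric(agg_m)[o])
}

# all k-part compositions of n (rows sum to n)
.compositions <- function(n, k) {
  if (k == 1) return(matrix(n, 1, 1))
  out <- list()
  for (first in 0:n) {
    rest <- .compositions(n - first, k - 1)
    out[[length(out) + 1]] <- cbind(first, rest)
  }
  m <- do.call(rbind, out)
  dimnames(m) <- NULL
  m
}

# proportional-allocation oracle for shared-peak partitioning
proportional_allocation <- function(ea_oip, ta_i, ea_r, ta_r) {
  dea <- ta_i * ea_r / ta_r
  ea_oip * dea / sum(dea)
}

myoglobin_sequence <- function() {
  read_proteins(test_path_extdata("MYG_HORSE.fasta"))[[1]]
}

test_path_extdata <- function(file) {
  system.file("extdata", file, package = "oiecare", mustWork = TRUE)
}

worked_example_report <- function() {
  read_report(test_path_extdata("oip_worked_example_match_report.tsv"))
}

# random proteoform over the 20 standard residues
random_proteoform <- function(n, id = "RND", with_ptm = FALSE) {
  aa <- c("G","A","S","P","V","T","C","L","I","N",
          "D","Q","K","E","M","H","F","R","Y","W")
  seq <- paste0(sample(aa, n, replace = TRUE), collapse = "")
  ptms <- if (with_ptm)
    data.frame(site = sample(n, 1), name = "ac", delta_formula = "C2H2O")
  proteoform(id, seq, ptms)
}
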