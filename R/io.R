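# Readers and writers: spectra (MGF / plain TSV / mzML), FASTA, the PTM
# sidecar, the on-disk ion database and the report tables.

.read_lines_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || all(!nzchar(trimws(lines))))
    stop("empty file: ", path)
  lines
}

.parse_mgf <- function(lines, path) {
  spectra <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "BEGIN IONS") {
      meta <- list(scan_id = "", precursor_mz = NA_real_,
                   precursor_charge = NA_integer_, rt = NA_real_)
      mzs <- numeric(0); abs <- numeric(0)
      i <- i + 1L
      while (i <= length(lines) && trimws(lines[i]) != "END IONS") {
        ln <- trimws(lines[i])
        if (grepl("^TITLE=", ln)) {
          meta$scan_id <- sub("^TITLE=", "", ln)
        } else if (grepl("^PEPMASS=", ln)) {
          meta$precursor_mz <- as.numeric(strsplit(sub("^PEPMASS=", "", ln),
                                                   "[[:space:]]+")[[1]][1])
        } else if (grepl("^CHARGE=", ln)) {
          meta$precursor_charge <- as.integer(sub("\\+$", "",
                                                  sub("^CHARGE=", "", ln)))
        } else if (grepl("^RTINSECONDS=", ln)) {
          meta$rt <- as.numeric(sub("^RTINSECONDS=", "", ln))
        } else if (nzchar(ln) && !grepl("^[A-Z]+=", ln)) {
          v <- suppressWarnings(
            as.numeric(strsplit(ln, "[[:space:]]+")[[1]]))
          if (length(v) < 2 || anyNA(v[1:2]))
            stop("malformed peak line in ", path, ": ", ln)
          mzs <- c(mzs, v[1]); abs <- c(abs, v[2])
        }
        i <- i + 1L
      }
      if (i > length(lines)) stop("unterminated BEGIN IONS block in ", path)
      spectra[[length(spectra) + 1]] <- centroid_spectrum(
        mzs, abs, precursor_mz = meta$precursor_mz,
        precursor_charge = meta$precursor_charge,
        scan_id = meta$scan_id, rt = meta$rt)
    }
    i <- i + 1L
  }
  if (length(spectra) == 0) stop("no spectra found in ", path)
  spectra
}

.parse_peak_tsv <- function(lines, path) {
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  df <- utils::read.table(text = lines, header = TRUE, sep = "\t")
  need <- c("mz", "abundance")
  if (!all(need %in% names(df)))
    stop("peak-list TSV must have columns mz, abundance: ", path)
  list(centroid_spectrum(df$mz, df$abundance,
                         scan_id = basename(path)))
}

.read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the mzR package")
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h))
  hdr <- mzR::header(h)
  if (nrow(hdr) == 0) stop("no spectra found in ", path)
  if (any(!hdr$centroided, na.rm = TRUE))
    stop("profile-mode spectra are not supported; centroid the data first")
  pk <- mzR::peaks(h)
  if (is.matrix(pk)) pk <- list(pk)
  lapply(seq_along(pk), function(i) {
    centroid_spectrum(pk[[i]][, 1], pk[[i]][, 2],
                      precursor_mz = if ("precursorMZ" %in% names(hdr) &&
                                         hdr$precursorMZ[i] > 0)
                        hdr$precursorMZ[i] else NA_real_,
                      precursor_charge = if ("precursorCharge" %in% names(hdr) &&
                                             hdr$precursorCharge[i] > 0)
                        hdr$precursorCharge[i] else NA_integer_,
                      scan_id = as.character(hdr$acquisitionNum[i]),
                      rt = hdr$retentionTime[i])
  })
}

#' Read centroided tandem mass spectra
#'
#' Supports MGF, plain peak-list TSV (columns `mz`, `abundance`; one
#' spectrum per file) and centroided mzML (via the mzR package). Profile
#' mzML data is rejected. The format is inferred from the file extension
#' unless given.
#'
#' @param path Input file.
#' @param format `"auto"`, `"mgf"`, `"tsv"` or `"mzml"`.
#' @return A list of `centroid_spectrum` objects.
#' @export
read_spectra <- function(path, format = c("auto", "mgf", "tsv", "mzml")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mgf = "mgf", tsv = "tsv", txt = "tsv",
                     mzml = "mzml",
                     stop("cannot infer spectrum format from extension: ",
                          ext))
  }
  if (format == "mzml") return(.read_mzml(path))
  lines <- .read_lines_checked(path)
  switch(format,
         mgf = .parse_mgf(lines, path),
         tsv = .parse_peak_tsv(lines, path))
}

#' Write spectra to an MGF file
#'
#' @param spectra A list of `centroid_spectrum` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", s$scan_id), con)
    if (!is.na(s$precursor_mz))
      writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz), con)
    if (!is.na(s$precursor_charge))
      writeLines(sprintf("CHARGE=%d+", s$precursor_charge), con)
    if (!is.na(s$rt))
      writeLines(sprintf("RTINSECONDS=%.3f", s$rt), con)
    writeLines(sprintf("%.6f\t%.6f", s$mz, s$abundance), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Read protein sequences from a FASTA file
#'
#' The protein id is the first whitespace-delimited token of the header.
#'
#' @param path FASTA file.
#' @return A named character vector of sequences.
#' @export
read_proteins <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) stop("no FASTA records in ", path)
  seqs <- as.character(aa)
  names(seqs) <- vapply(strsplit(names(aa), "[[:space:]]+"), `[[`, "", 1)
  seqs
}

#' Read a PTM annotation sidecar
#'
#' Tab-separated with header columns `accession`, `site`, `name`,
#' `delta_formula`. Each row annotates one candidate PTM site; sites are
#' expanded dynamically into proteoforms by [expand_proteoforms()].
#'
#' @param path Sidecar TSV.
#' @return A data.frame split-able by accession.
#' @export
read_ptm_annotations <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("accession", "site", "name", "delta_formula")
  if (!all(need %in% names(df)))
    stop("PTM sidecar must have columns: ", paste(need, collapse = ", "))
  df$site <- as.integer(df$site)
  df
}

#' Build the proteoform database from FASTA plus PTM sidecar
#'
#' @param fasta Path to the protein FASTA.
#' @param ptm_sidecar Optional path to the PTM annotation TSV.
#' @param k_max Per-protein cap on annotated sites (see
#'   [expand_proteoforms()]).
#' @return A list of `proteoform` objects.
#' @export
load_proteoforms <- function(fasta, ptm_sidecar = NULL, k_max = 10L) {
  seqs <- read_proteins(fasta)
  ann <- if (!is.null(ptm_sidecar)) read_ptm_annotations(ptm_sidecar)
  out <- list()
  for (acc in names(seqs)) {
    a <- if (!is.null(ann)) ann[ann$accession == acc, , drop = FALSE]
    if (!is.null(a) && nrow(a) == 0) a <- NULL
    out <- c(out, expand_proteoforms(acc, seqs[[acc]], a, k_max = k_max))
  }
  out
}

# ---- ion database on disk ---------------------------------------------------

#' Write an ion database as columnar TSV
#'
#' Columns: `label`, `series`, `index`, `nl`, `charge`, `base_mz`,
#' `mono_mz`, `peaks` (envelope serialized as `"mz:rel;..."`).
#'
#' @param db An `ion_db`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_ion_database <- function(db, path) {
  peaks <- vapply(db$envelope, function(e)
    paste(sprintf("%.6f:%.4f", e$mz, e$rel), collapse = ";"), "")
  out <- data.frame(label = db$label, series = db$series, index = db$index,
                    nl = db$nl, charge = db$charge,
                    base_mz = sprintf("%.6f", db$base_mz),
                    mono_mz = sprintf("%.6f", db$mono_mz),
                    peaks = peaks, stringsAsFactors = FALSE)
  for (extra in c("protein_id", "ptm_string"))
    if (extra %in% names(db)) out[[extra]] <- db[[extra]]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ion database written by [write_ion_database()]
#'
#' @param path Ion-database TSV.
#' @return An `ion_db`.
#' @export
read_ion_database <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  # keep row order aligned with the sort applied by the constructor
  df <- df[order(as.numeric(df$base_mz)), , drop = FALSE]
  rows <- lapply(seq_len(nrow(df)), function(i) {
    pk <- strsplit(df$peaks[i], ";")[[1]]
    parts <- do.call(rbind, strsplit(pk, ":"))
    mz <- as.numeric(parts[, 1]); rel <- as.numeric(parts[, 2])
    env <- structure(list(mz = mz, rel = rel,
                          charge = df$charge[i],
                          monoisotopic_mz = mz[1],
                          base_index = which.max(rel)),
                     class = "theo_envelope")
    list(label = df$label[i], series = df$series[i], index = df$index[i],
         nl = df$nl[i], charge = df$charge[i],
         base_mz = as.numeric(df$base_mz[i]),
         mono_mz = as.numeric(df$mono_mz[i]), envelope = env)
  })
  out <- .ion_db(rows)
  for (extra in c("protein_id", "ptm_string"))
    if (extra %in% names(df)) out[[extra]] <- df[[extra]]
  out
}

# ---- reports and config -----------------------------------------------------

#' Write a report table as TSV
#' @param df A data.frame.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a report table written by [write_report()]
#' @param path Report TSV.
#' @return A data.frame.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Read a flat key=value configuration file
#'
#' Recognized keys mirror [default_config()]: e.g.
#' `product.ipaco`, `product.ipmd`, `product.ipad`, `precursor.ipaco`,
#' `series` (comma-separated), `losses` (`none`, `all` or comma-separated),
#' `max_product_charge`, `pmp_min`, `fdr_alpha`, `decoy_mode`,
#' `decoy_seed`, `resolve` (`true`/`false`). Unknown keys are an error;
#' unset keys keep their defaults.
#'
#' @param path Config file; `NULL` returns the defaults.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  lines <- .read_lines_checked(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    set_tol <- function(scope, field) {
      cfg[[scope]][[field]] <<- as.numeric(val)
      # re-validate
      cfg[[scope]] <<- search_params(cfg[[scope]]$ipaco, cfg[[scope]]$ipmd,
                                     cfg[[scope]]$ipad, scope = scope)
    }
    switch(key,
      "precursor.ipaco" = set_tol("precursor", "ipaco"),
      "precursor.ipmd" = set_tol("precursor", "ipmd"),
      "precursor.ipad" = set_tol("precursor", "ipad"),
      "product.ipaco" = set_tol("product", "ipaco"),
      "product.ipmd" = set_tol("product", "ipmd"),
      "product.ipad" = set_tol("product", "ipad"),
      "series" = { cfg$series <- strsplit(val, ",")[[1]] },
      "losses" = {
        cfg$losses <- if (val == "none") character(0)
                      else if (val == "all") "all"
                      else strsplit(val, ",")[[1]]
      },
      "max_product_charge" = { cfg$max_product_charge <- as.integer(val) },
      "pmp_min" = { cfg$pmp_min <- as.numeric(val) },
      "fdr_alpha" = { cfg$fdr_alpha <- as.numeric(val) },
      "decoy_mode" = { cfg$decoy_mode <- val },
      "decoy_seed" = { cfg$decoy_seed <- as.integer(val) },
      "resolve" = { cfg$resolve <- tolower(val) %in% c("true", "1", "yes") },
      "precursor_check" = {
        cfg$precursor_check <- tolower(val) %in% c("true", "1", "yes") },
      stop("unknown config key: ", key))
  }
  cfg
}
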