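testday_cols <- c("cow", "lactation", "dim", "test_year", "test_month",
                  "herd", "milk", "fat", "protein", "age_calving",
                  "hf_fraction", "calving_month", "sire_known")

#' Read / write test-day record CSV
#'
#' Comma-separated with header; one row per cow-lactation-DIM test. Fat and
#' protein fields may be empty (missing on some tests); empty fields become
#' `NA`. Columns: `cow`, `lactation` (1-3), `dim`, `test_year`,
#' `test_month`, `herd`, `milk`, `fat`, `protein`, `age_calving` (months),
#' `hf_fraction` (Holstein-Friesian blood fraction in \[0,1\]),
#' `calving_month`, `sire_known` (logical).
#'
#' @param path File path.
#' @param lactations Admissible lactation numbers (default 1:3).
#' @return [read_testday()]: tibble of typed records.
#' @export
read_testday <- function(path, lactations = 1:3) {
  rec <- readr::read_csv(
    path,
    col_types = readr::cols(
      cow = readr::col_integer(),
      lactation = readr::col_integer(),
      dim = readr::col_integer(),
      test_year = readr::col_integer(),
      test_month = readr::col_integer(),
      herd = readr::col_integer(),
      milk = readr::col_double(),
      fat = readr::col_double(),
      protein = readr::col_double(),
      age_calving = readr::col_double(),
      hf_fraction = readr::col_double(),
      calving_month = readr::col_integer(),
      sire_known = readr::col_logical()
    ),
    na = c("", "NA")
  )
  validate_testday(rec, lactations = lactations)
}

validate_testday <- function(rec, lactations = 1:3) {
  rec <- tibble::as_tibble(rec)
  missing_cols <- setdiff(setdiff(testday_cols, "sire_known"), names(rec))
  if (length(missing_cols)) {
    abort(paste("test-day table lacks column(s):",
                paste(missing_cols, collapse = ", ")))
  }
  if (!"sire_known" %in% names(rec)) rec$sire_known <- TRUE
  bad <- which(!rec$lactation %in% lactations)
  if (length(bad)) {
    abort(sprintf("row %d: lactation %d outside {%s}.",
                  bad[1], rec$lactation[bad[1]],
                  paste(lactations, collapse = ",")))
  }
  bad <- which(is.na(rec$dim) | rec$dim <= 0L)
  if (length(bad)) abort(sprintf("row %d: DIM must be positive.", bad[1]))
  bad <- which(is.na(rec$milk))
  if (length(bad)) {
    abort(sprintf("row %d: milk yield missing or non-numeric.", bad[1]))
  }
  for (tr in c("milk", "fat", "protein")) {
    bad <- which(!is.na(rec[[tr]]) & rec[[tr]] < 0)
    if (length(bad)) abort(sprintf("row %d: negative %s yield.", bad[1], tr))
  }
  rec[testday_cols]
}

#' @param records Test-day tibble.
#' @rdname read_testday
#' @return [write_testday()]: `path`, invisibly.
#' @export
write_testday <- function(records, path) {
  readr::write_csv(records[testday_cols], path, na = "")
  invisible(path)
}

#' Run configuration
#'
#' Bundles model, Gibbs-chain, solver and record-edit settings with the
#' invariants checked (chain > burn-in >= 0, thinning >= 1, DIM min < max,
#' order >= 1). [read_run_config()] loads the same structure from YAML.
#' The `"paper"` Gibbs preset is chain 200,000 / burn-in 50,000 / thinning
#' 20; the desk-scale default is 20,000 / 5,000 / 10.
#'
#' @param model List: `traits`, `lactations`, `order`, `dim_range`.
#' @param gibbs List: `chain`, `burn_in`, `thin`, `seed`, or the string
#'   `"paper"` for the published protocol.
#' @param pcg List: `tol`, `max_iter`.
#' @param edits Edit thresholds, see [edit_rules()].
#' @param paths Optional named list of file paths.
#' @return Object of class `run_config`.
#' @export
run_config <- function(model = list(), gibbs = list(), pcg = list(),
                       edits = list(), paths = list()) {
  if (identical(gibbs, "paper")) {
    gibbs <- list(chain = 200000L, burn_in = 50000L, thin = 20L)
  }
  model <- utils::modifyList(
    list(traits = c("milk", "fat", "protein"), lactations = 1:3,
         order = 5L, dim_range = c(5L, 305L)), model)
  gibbs <- utils::modifyList(
    list(chain = 20000L, burn_in = 5000L, thin = 10L, seed = 1L), gibbs)
  pcg <- utils::modifyList(list(tol = 1e-10, max_iter = 5000L), pcg)
  edits <- do.call(edit_rules, edits)
  if (gibbs$chain <= gibbs$burn_in || gibbs$burn_in < 0) {
    abort("gibbs: need chain > burn_in >= 0.")
  }
  if (gibbs$thin < 1) abort("gibbs: thinning must be >= 1.")
  if (model$order < 1) abort("model: polynomial order must be >= 1.")
  if (model$dim_range[1] >= model$dim_range[2]) {
    abort("model: DIM range needs min < max.")
  }
  structure(list(model = model, gibbs = gibbs, pcg = pcg, edits = edits,
                 paths = paths),
            class = "run_config")
}

#' @param path YAML file path.
#' @rdname run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y[intersect(names(y),
                                  c("model", "gibbs", "pcg", "edits",
                                    "paths"))])
}

#' Write result tables
#'
#' Writes the derived-parameter and breeding-value tables of a finished run
#' as CSV files into `dir`: variance components with posterior SDs
#' (`variance_components.csv`), daily and 305-d heritabilities
#' (`heritability_daily.csv`, `heritability_305d.csv`), 305-d
#' additive-genetic and permanent-environmental correlation matrices
#' (`cor_ag_305d.csv`, `cor_pe_305d.csv`), EBVs (`ebv.csv`) and, when
#' supplied, genetic-trend regressions (`trend.csv`).
#'
#' @param params A `genetic_parameters` object from [genetic_parameters()].
#' @param ebv EBV tibble from [extract_ebv()] (may have zero rows).
#' @param dir Output directory (created if absent).
#' @param components Optional posterior summary tibble (e.g.
#'   `tidy(gibbs_fit)`).
#' @param trend Optional trend fit from [genetic_trend()].
#' @return Named character vector of the files written, invisibly.
#' @export
write_results <- function(params, ebv, dir, components = NULL, trend = NULL) {
  stopifnot(inherits(params, "genetic_parameters"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  out <- c()
  readr::write_csv(params$daily, p("heritability_daily.csv"))
  out["daily"] <- p("heritability_daily.csv")
  readr::write_csv(params$h2_305, p("heritability_305d.csv"))
  out["h305"] <- p("heritability_305d.csv")
  readr::write_csv(cor_to_tibble(params$cor_ag_305), p("cor_ag_305d.csv"))
  out["cor_ag"] <- p("cor_ag_305d.csv")
  readr::write_csv(cor_to_tibble(params$cor_pe_305), p("cor_pe_305d.csv"))
  out["cor_pe"] <- p("cor_pe_305d.csv")
  ebv_flat <- ebv
  if ("coef" %in% names(ebv_flat)) {
    cf <- do.call(rbind, ebv_flat$coef)
    if (is.null(cf)) cf <- matrix(numeric(0), 0, 0)
    if (ncol(cf) > 0) colnames(cf) <- paste0("coef", seq_len(ncol(cf)))
    ebv_flat <- dplyr::bind_cols(ebv_flat[setdiff(names(ebv_flat), "coef")],
                                 tibble::as_tibble(cf))
  }
  readr::write_csv(ebv_flat, p("ebv.csv"))
  out["ebv"] <- p("ebv.csv")
  if (!is.null(components)) {
    readr::write_csv(components, p("variance_components.csv"))
    out["components"] <- p("variance_components.csv")
  }
  if (!is.null(trend)) {
    readr::write_csv(tibble::as_tibble(trend), p("trend.csv"))
    out["trend"] <- p("trend.csv")
  }
  invisible(out)
}

cor_to_tibble <- function(m) {
  tibble::as_tibble(m, rownames = "stratum")
}
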