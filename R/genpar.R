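#' Heritability from average variance components
#'
#' The defining ratio of the model: additive-genetic variance over the sum
#' of additive-genetic, permanent-environmental and residual variances.
#'
#' @param ag,pe,r Variance components (vectors recycle).
#' @return Numeric heritabilities.
#' @examples
#' h2_ratio(7.58, 5.97, 2.11)   # 0.48 to two decimals
#' @export
h2_ratio <- function(ag, pe, r) {
  ag / (ag + pe + r)
}

#' Daily variance curves
#'
#' Evaluates \eqn{v(t) = \phi(t)^\top G \phi(t)} for the additive-genetic
#' and permanent-environmental blocks of every trait-lactation stratum over
#' the DIM grid.
#'
#' @param covset A [covariance_set()].
#' @param basis A [legendre_basis()] matching the spec's order.
#' @return Tibble with `component` (`"ag"`/`"pe"`), `trait`, `lactation`,
#'   `dim`, `variance`.
#' @export
daily_variance <- function(covset, basis = NULL) {
  spec <- covset$spec
  basis <- basis %||% legendre_basis(spec$order, spec$dim_range)
  Phi <- basis$Phi
  per_stratum <- function(M, s) {
    B <- cov_block(M, spec, s)
    as.numeric(rowSums((Phi %*% B) * Phi))
  }
  purrr::map_dfr(seq_len(spec$n_strata), function(s) {
    tibble::tibble(
      component = rep(c("ag", "pe"), each = length(basis$dims)),
      trait = spec$strata$trait[s],
      lactation = spec$strata$lactation[s],
      dim = rep(basis$dims, 2L),
      variance = c(per_stratum(covset$G0, s), per_stratum(covset$P0, s))
    )
  })
}

#' Daily heritability curves and averages
#'
#' Daily heritability \eqn{h^2(t) = v_{AG}(t) / (v_{AG}(t) + v_{PE}(t) +
#' \sigma^2_R)} for every stratum, plus the two average conventions: the
#' mean of the daily ratios and the ratio of the average variances. The two
#' agree closely (within about 0.01-0.02) at realistic variance magnitudes;
#' the ratio-of-averages convention is the one comparable to published
#' average daily heritability tables.
#'
#' @inheritParams daily_variance
#' @return Tibble with `trait`, `lactation`, `dim`, `v_ag`, `v_pe`, `v_r`,
#'   `h2`; the per-stratum averages are attached as attribute `"averages"`
#'   and returned by [average_daily_h2()].
#' @export
daily_h2 <- function(covset, basis = NULL) {
  spec <- covset$spec
  basis <- basis %||% legendre_basis(spec$order, spec$dim_range)
  dv <- daily_variance(covset, basis) |>
    tidyr::pivot_wider(names_from = "component", values_from = "variance",
                       names_prefix = "v_")
  dv$v_r <- covset$R[stratum_of(spec, dv$trait, dv$lactation)]
  dv$h2 <- h2_ratio(dv$v_ag, dv$v_pe, dv$v_r)
  avg <- dv |>
    dplyr::group_by(.data$trait, .data$lactation) |>
    dplyr::summarise(
      h2_mean_of_ratios = mean(.data$h2),
      h2_ratio_of_means = h2_ratio(mean(.data$v_ag), mean(.data$v_pe),
                                   mean(.data$v_r)),
      .groups = "drop"
    )
  attr(dv, "averages") <- avg
  dv
}

#' @inheritParams daily_variance
#' @rdname daily_h2
#' @return [average_daily_h2()]: tibble with `trait`, `lactation`,
#'   `h2_mean_of_ratios`, `h2_ratio_of_means`.
#' @export
average_daily_h2 <- function(covset, basis = NULL) {
  attr(daily_h2(covset, basis), "averages")
}

#' 305-day aggregates: variances, heritabilities, correlations
#'
#' Aggregates the coefficient (co)variances over the DIM grid with the
#' summing vector: \eqn{AG_{305}(i,j) = S^\top G_{ij} S} (PE analogous).
#' 305-d heritability divides by the total including the accumulated
#' residual `ndays * sigma^2_R` (independent daily residuals); set
#' `residual = "omit"` to exclude it. Correlations come from the aggregate
#' stratum x stratum matrices.
#'
#' @inheritParams daily_variance
#' @param residual `"accumulate"` (default) or `"omit"`.
#' @return List of class `aggregate_305`: `summary` tibble (`trait`,
#'   `lactation`, `ag_305`, `pe_305`, `r_305`, `h2_305`), matrices
#'   `ag_cov`, `pe_cov`, `ag_cor`, `pe_cor` with stratum dimnames.
#' @export
aggregate_305d <- function(covset, basis = NULL,
                           residual = c("accumulate", "omit")) {
  residual <- match.arg(residual)
  spec <- covset$spec
  basis <- basis %||% legendre_basis(spec$order, spec$dim_range)
  S <- summing_vector(basis)
  ns <- spec$n_strata
  Sfull <- matrix(0, spec$n_coef, ns)
  for (s in seq_len(ns)) Sfull[stratum_cols(spec, s), s] <- S
  ag <- t(Sfull) %*% covset$G0 %*% Sfull
  pe <- t(Sfull) %*% covset$P0 %*% Sfull
  lab <- paste0(spec$strata$trait, "_l", spec$strata$lactation)
  dimnames(ag) <- dimnames(pe) <- list(lab, lab)
  ndays <- length(basis$dims)
  r305 <- if (residual == "accumulate") ndays * covset$R else rep(0, ns)
  summary <- tibble::tibble(
    trait = spec$strata$trait,
    lactation = spec$strata$lactation,
    ag_305 = unname(diag(ag)),
    pe_305 = unname(diag(pe)),
    r_305 = r305,
    h2_305 = unname(diag(ag) / (diag(ag) + diag(pe) + r305))
  )
  structure(
    list(summary = summary, ag_cov = ag, pe_cov = pe,
         ag_cor = stats::cov2cor(ag), pe_cor = stats::cov2cor(pe),
         residual = residual),
    class = "aggregate_305"
  )
}

#' Correlation surface over days in milk
#'
#' The correlation between stratum `i` at DIM `s` and stratum `j` at DIM
#' `t`: \eqn{r(s,t) = \phi(s)^\top G_{ij} \phi(t) / \sqrt{\phi(s)^\top
#' G_{ii} \phi(s)\; \phi(t)^\top G_{jj} \phi(t)}}. The default grid is the
#' six DIM 5, 65, 125, 185, 245, 305 used in published tables; `grid =
#' "full"` evaluates every day.
#'
#' @inheritParams daily_variance
#' @param component `"ag"` or `"pe"`.
#' @param trait_i,lactation_i,trait_j,lactation_j Stratum selectors
#'   (defaults: first stratum against itself).
#' @param grid Integer DIM vector or `"full"`.
#' @return Tibble with `dim_i`, `dim_j`, `correlation`.
#' @export
correlation_surface <- function(covset, basis = NULL, component = c("ag", "pe"),
                                trait_i = NULL, lactation_i = NULL,
                                trait_j = NULL, lactation_j = NULL,
                                grid = c(5L, 65L, 125L, 185L, 245L, 305L)) {
  component <- match.arg(component)
  spec <- covset$spec
  basis <- basis %||% legendre_basis(spec$order, spec$dim_range)
  trait_i <- trait_i %||% spec$strata$trait[1]
  lactation_i <- lactation_i %||% spec$strata$lactation[1]
  trait_j <- trait_j %||% trait_i
  lactation_j <- lactation_j %||% lactation_i
  si <- stratum_of(spec, trait_i, lactation_i)
  sj <- stratum_of(spec, trait_j, lactation_j)
  if (identical(grid, "full")) grid <- basis$dims
  grid <- as.integer(grid)
  M <- if (component == "ag") covset$G0 else covset$P0
  Pg <- leg_covariables(basis, grid)
  cov_ij <- Pg %*% cov_block(M, spec, si, sj) %*% t(Pg)
  v_i <- rowSums((Pg %*% cov_block(M, spec, si)) * Pg)
  v_j <- rowSums((Pg %*% cov_block(M, spec, sj)) * Pg)
  r <- cov_ij / sqrt(outer(v_i, v_j))
  tibble::tibble(
    dim_i = rep(grid, times = length(grid)),
    dim_j = rep(grid, each = length(grid)),
    correlation = as.numeric(r)
  )
}

#' Genetic trend by regression of yearly mean EBV on birth year
#'
#' For each trait-lactation, averages the EBVs of all animals born in each
#' year and fits ordinary least squares of the yearly mean on birth year
#' (years weighted equally). The slope is the realized genetic trend in kg
#' per year of 305-d yield.
#'
#' @param ebv EBV tibble from [extract_ebv()].
#' @param birth_years Either a pedigree tibble with `animal` and
#'   `birth_year`, or a numeric vector named/ordered like `ebv$animal`.
#' @return Tibble of class `trend_fit`: `trait`, `lactation`, `intercept`,
#'   `slope`, `se_intercept`, `se_slope`, `r_squared`, `n_years`.
#' @export
genetic_trend <- function(ebv, birth_years) {
  if (is.data.frame(birth_years)) {
    by <- birth_years$birth_year[match(ebv$animal, birth_years$animal)]
  } else {
    by <- rep_len(as.numeric(birth_years), nrow(ebv))
  }
  dat <- ebv |>
    dplyr::mutate(birth_year = by) |>
    dplyr::filter(!is.na(.data$birth_year))
  if (dplyr::n_distinct(dat$birth_year) < 2L) {
    abort("genetic trend needs EBVs from at least two distinct birth years.")
  }
  out <- dat |>
    dplyr::group_by(.data$trait, .data$lactation, .data$birth_year) |>
    dplyr::summarise(mean_ebv = mean(.data$ebv), .groups = "drop") |>
    dplyr::group_by(.data$trait, .data$lactation) |>
    dplyr::group_modify(function(d, key) {
      fit <- lm(mean_ebv ~ birth_year, data = d)
      sm <- summary(fit)
      tibble::tibble(
        intercept = unname(coef(fit)[1]),
        slope = unname(coef(fit)[2]),
        se_intercept = sm$coefficients[1, 2],
        se_slope = sm$coefficients[2, 2],
        r_squared = sm$r.squared,
        n_years = nrow(d)
      )
    }) |>
    dplyr::ungroup()
  class(out) <- c("trend_fit", class(out))
  out
}

#' Bundle all derived genetic parameters
#'
#' Computes, from one covariance set, the tables a genetic evaluation
#' reports: daily heritability curves, average daily heritabilities (both
#' conventions), 305-d variances/heritabilities and 305-d correlation
#' matrices.
#'
#' @inheritParams aggregate_305d
#' @return List of class `genetic_parameters` with elements `daily`,
#'   `averages`, `h2_305`, `cor_ag_305`, `cor_pe_305`, `agg`.
#' @export
genetic_parameters <- function(covset, basis = NULL,
                               residual = c("accumulate", "omit")) {
  daily <- daily_h2(covset, basis)
  agg <- aggregate_305d(covset, basis, residual)
  structure(
    list(daily = daily, averages = attr(daily, "averages"),
         h2_305 = agg$summary, cor_ag_305 = agg$ag_cor,
         cor_pe_305 = agg$pe_cor, agg = agg),
    class = "genetic_parameters"
  )
}

#' @export
print.genetic_parameters <- function(x, ...) {
  cat("<genetic_parameters>\naverage daily h2 (ratio of mean variances):\n")
  print(as.data.frame(x$averages), digits = 3)
  cat("305-d h2:\n")
  print(as.data.frame(x$h2_305[, c("trait", "lactation", "h2_305")]),
        digits = 3)
  invisible(x)
}
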