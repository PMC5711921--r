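#' Convert a Spearman rank correlation to a latent Pearson correlation
#'
#' Under a Gaussian copula the Spearman correlation of two continuous
#' margins relates to the latent Pearson correlation by
#' `r = 2 * sin(pi * rho_s / 6)`. The generator uses this identity so the
#' planted Spearman targets survive the margin transforms.
#'
#' @param rho_s Spearman rho, `|rho_s| <= 1`.
#' @return Latent Pearson correlation.
#' @export
#' @examples
#' spearman_to_pearson(c(0, 0.5, 1))
spearman_to_pearson <- function(rho_s) {
  if (any(abs(rho_s) > 1)) stop("|rho_s| must be <= 1", call. = FALSE)
  2 * sin(pi * rho_s / 6)
}

#' Marginal distribution descriptors for the cohort simulator
#'
#' Each descriptor is a quantile transform applied to latent normal
#' quantiles, so the transforms are monotone and rank-preserving:
#' `marginal_normal()` and `marginal_lognormal()` are strictly monotone;
#' `marginal_integer_uniform()` (e.g. age in whole years) and
#' `marginal_zicount()` (zero-inflated counts such as urine cell counts)
#' introduce ties, which attenuates the realized rank correlation the way
#' tied clinical measurements do.
#'
#' @param mean,sd,meanlog,sdlog,min,max,p0,lambda Distribution parameters;
#'   `p0` is the structural zero probability of the zero-inflated Poisson.
#' @return A marginal descriptor (list with class `osteomir_marginal`).
#' @name marginals
NULL

new_marginal <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "osteomir_marginal")
}

#' @rdname marginals
#' @export
marginal_normal <- function(mean, sd) new_marginal("normal", mean = mean, sd = sd)

#' @rdname marginals
#' @export
marginal_lognormal <- function(meanlog, sdlog) {
  new_marginal("lognormal", meanlog = meanlog, sdlog = sdlog)
}

#' @rdname marginals
#' @export
marginal_integer_uniform <- function(min, max) {
  new_marginal("integer-uniform", min = min, max = max)
}

#' @rdname marginals
#' @export
marginal_zicount <- function(p0, lambda) {
  new_marginal("zero-inflated-count", p0 = p0, lambda = lambda)
}

#' Transform latent normal quantiles into a target margin
#'
#' @param descriptor A descriptor from [marginals].
#' @param latent Numeric vector of latent standard-normal draws.
#' @return Numeric vector with the descriptor's marginal distribution.
#' @export
plant_skewed_margin <- function(descriptor, latent) {
  if (!inherits(descriptor, "osteomir_marginal")) {
    stop("unknown marginal descriptor", call. = FALSE)
  }
  u <- stats::pnorm(latent)
  switch(descriptor$kind,
    "normal" = stats::qnorm(u, descriptor$mean, descriptor$sd),
    "lognormal" = stats::qlnorm(u, descriptor$meanlog, descriptor$sdlog),
    "integer-uniform" = {
      k <- descriptor$max - descriptor$min + 1L
      descriptor$min + pmin(floor(u * k), k - 1)
    },
    "zero-inflated-count" = {
      u2 <- pmax((u - descriptor$p0) / (1 - descriptor$p0), 0)
      ifelse(u < descriptor$p0, 0, stats::qpois(u2, descriptor$lambda))
    },
    stop("unknown marginal descriptor kind: ", descriptor$kind, call. = FALSE)
  )
}

default_marginals <- function() {
  list(
    bmd = marginal_normal(0.85, 0.12),
    mir194 = marginal_lognormal(0, 0.6),
    age = marginal_integer_uniform(48, 66),
    height = marginal_normal(158, 5.5),
    weight = marginal_normal(63, 8.5),
    ALT = marginal_lognormal(log(16), 0.55),
    AST = marginal_lognormal(log(20), 0.40),
    GGT = marginal_lognormal(log(20), 0.60),
    ALP = marginal_normal(75, 18),
    LDH = marginal_normal(180, 35),
    UA = marginal_normal(290, 65),
    CKMB_CK = marginal_lognormal(log(0.10), 0.40),
    TBIL = marginal_lognormal(log(11), 0.35),
    DBIL = marginal_lognormal(log(3.5), 0.35),
    ALB = marginal_normal(42, 3.5),
    TP = marginal_normal(70, 5),
    BUN = marginal_normal(5.4, 1.3),
    CREA = marginal_normal(62, 12),
    GLU = marginal_lognormal(log(5.4), 0.18),
    TC = marginal_normal(5.0, 0.9),
    TG = marginal_lognormal(log(1.4), 0.45),
    HDL = marginal_normal(1.35, 0.30),
    LDL = marginal_normal(2.9, 0.8),
    WBC = marginal_normal(6.2, 1.5),
    RBC = marginal_normal(4.3, 0.4),
    HGB = marginal_normal(130, 11),
    PLT = marginal_normal(220, 55),
    NEUT = marginal_normal(60, 8),
    LVDS = marginal_normal(30, 3),
    LVEDD = marginal_normal(47, 4),
    EF = marginal_normal(63, 5),
    FS = marginal_normal(34, 4),
    AO = marginal_normal(30, 3),
    LA = marginal_normal(33, 4),
    IVS = marginal_normal(9.5, 1.2),
    LVPW = marginal_normal(9.3, 1.1),
    E_A = marginal_normal(0.9, 0.25),
    U_EC = marginal_zicount(0.35, 4),
    U_ECH = marginal_zicount(0.45, 2),
    U_WBC = marginal_zicount(0.50, 2),
    U_RBC = marginal_zicount(0.60, 1.5),
    U_SG = marginal_normal(1.015, 0.005),
    U_PH = marginal_normal(6.0, 0.7),
    U_CAST = marginal_zicount(0.80, 0.8)
  )
}

#' Cohort simulator configuration
#'
#' Defines the statistical structure of a simulated postmenopausal cohort:
#' a continuous BMD outcome, the miR-194-5p marker, and 42 examination
#' items with planted Spearman correlations to BMD and one collinear
#' echocardiography pair (LVDS-LVEDD, rho 0.63).
#'
#' Defaults emulate the study cohort: marker rho -0.365 with BMD; age and
#' weight weakly correlated (-0.25 / +0.25); the eight minor
#' BMD-correlated items (LVDS, LVEDD, ALT, U_EC, UA, U_ECH, CKMB_CK, GGT)
#' planted at |rho| 0.18, the centre of the extremely-weak band consistent
#' with per-item significance at n = 230; all remaining items null.
#' Bone-status class proportions default to 40/34.3/25.7 percent
#' (normal/osteopenia/osteoporosis), applied to BMD as quantile cuts with
#' largest-remainder rounding so class counts are exact.
#'
#' @param n Number of participants.
#' @param class_proportions Length-3 numeric summing to 1:
#'   normal, osteopenia, osteoporosis.
#' @param target_spearman Named numeric vector of Spearman targets with
#'   BMD; names are `mir194` and registry item names. Unnamed items are 0.
#' @param collinear_pairs List of `list(a, b, rho)` planting a Spearman
#'   correlation between two items.
#' @param marginals Named list of [marginals] descriptors; defaults cover
#'   bmd, mir194, and all 42 registry items.
#' @param registry Item registry tibble.
#' @param id_prefix Prefix for generated participant ids.
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n = 230,
                              class_proportions = c(normal = 0.400,
                                                    osteopenia = 0.343,
                                                    osteoporosis = 0.257),
                              target_spearman = c(
                                mir194 = -0.365,
                                age = -0.25, weight = 0.25,
                                LVDS = -0.18, LVEDD = -0.18, ALT = -0.18,
                                U_EC = -0.18, UA = 0.18, U_ECH = -0.18,
                                CKMB_CK = 0.18, GGT = -0.18),
                              collinear_pairs = list(
                                list(a = "LVDS", b = "LVEDD", rho = 0.63)),
                              marginals = default_marginals(),
                              registry = default_item_registry(),
                              id_prefix = "S") {
  stopifnot(n >= 5, length(class_proportions) == 3)
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    stop("class_proportions must sum to 1", call. = FALSE)
  }
  if (any(abs(target_spearman) >= 1)) {
    stop("every target rho must be in (-1, 1)", call. = FALSE)
  }
  unknown <- setdiff(names(target_spearman), c("mir194", registry$item))
  if (length(unknown) > 0L) {
    stop("target for unknown item(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(list(n = n, class_proportions = class_proportions,
                 target_spearman = target_spearman,
                 collinear_pairs = collinear_pairs, marginals = marginals,
                 registry = registry, id_prefix = id_prefix),
            class = "cohort_sim_config")
}

# Largest-remainder apportionment of n into round(n * p) with exact total.
largest_remainder <- function(n, props) {
  raw <- n * props
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Clamp a symmetric matrix to the nearest correlation matrix by
# eigenvalue clipping followed by diagonal rescaling.
nearest_psd_correlation <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) > 1e-10) return(R)
  v <- pmax(e$values, 1e-8)
  R2 <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- sqrt(diag(R2))
  R2 <- R2 / tcrossprod(d)
  diag(R2) <- 1
  R2
}

build_latent_correlation <- function(config) {
  vars <- c("bmd", "mir194", config$registry$item)
  d <- length(vars)
  R <- diag(d)
  dimnames(R) <- list(vars, vars)
  for (nm in names(config$target_spearman)) {
    r <- spearman_to_pearson(config$target_spearman[[nm]])
    R["bmd", nm] <- R[nm, "bmd"] <- r
  }
  for (p in config$collinear_pairs) {
    r <- spearman_to_pearson(p$rho)
    R[p$a, p$b] <- R[p$b, p$a] <- r
  }
  R2 <- nearest_psd_correlation(R)
  if (min(eigen(R2, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("latent correlation matrix is not positive semi-definite after ",
         "repair; check target_spearman and collinear_pairs", call. = FALSE)
  }
  R2
}

#' Simulate a seed-reproducible synthetic cohort
#'
#' Draws a Gaussian copula: a multivariate normal sample with latent
#' correlations from [spearman_to_pearson()] applied to the planted
#' Spearman targets, each margin then transformed by its (monotone)
#' quantile descriptor. The T-score is an affine map of BMD calibrated so
#' that the class-proportion quantile cuts of BMD land exactly on the
#' -2.5 and -1.0 diagnostic boundaries, giving exact class counts by
#' largest-remainder rounding. The same `(config, seed)` always yields an
#' identical table.
#'
#' @param n Number of participants (overrides `config$n`).
#' @param seed Integer seed.
#' @param config A [cohort_sim_config()].
#' @return A cohort tibble (as from [read_cohort()]) with attributes
#'   `provenance = "synthetic"` and `sim_config`.
#' @export
#' @examples
#' cohort <- simulate_cohort(n = 60, seed = 1)
#' table(cohort$status)
simulate_cohort <- function(n = config$n, seed = 1,
                            config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"), n >= 5)
  R <- build_latent_correlation(config)
  vars <- colnames(R)
  Z <- withr::with_seed(seed, {
    matrix(stats::rnorm(n * length(vars)), nrow = n) %*% chol(R)
  })
  colnames(Z) <- vars
  values <- purrr::map(vars, function(v) {
    desc <- config$marginals[[v]]
    if (is.null(desc)) stop("no marginal descriptor for '", v, "'",
                            call. = FALSE)
    plant_skewed_margin(desc, Z[, v])
  })
  names(values) <- vars
  cohort <- tibble::as_tibble(values)
  cohort$t_score <- t_score_from_bmd(cohort$bmd, config$class_proportions)
  cohort$id <- sprintf("%s%04d", config$id_prefix, seq_len(n))
  cohort$status <- classify_bone_status(cohort$t_score)
  cohort <- dplyr::relocate(cohort, "id", "mir194",
                            dplyr::all_of(config$registry$item),
                            "bmd", "t_score", "status")
  attr(cohort, "provenance") <- "synthetic"
  attr(cohort, "sim_config") <- config
  cohort
}

# Affine T-score map: the osteoporosis and osteopenia BMD quantile cuts
# (largest-remainder counts) land on -2.5 and -1.0 respectively.
t_score_from_bmd <- function(bmd, class_proportions) {
  n <- length(bmd)
  counts <- largest_remainder(n, rev(class_proportions)) # op, pen, normal
  k_op <- counts[1]; k_pen <- counts[2]
  if (k_op < 1 || k_pen < 1 || k_op + k_pen >= n) {
    stop("class proportions give an empty bone-status class at n = ", n,
         call. = FALSE)
  }
  s <- sort(bmd)
  c1 <- (s[k_op] + s[k_op + 1]) / 2          # osteoporosis boundary
  c2 <- (s[k_op + k_pen] + s[k_op + k_pen + 1]) / 2 # osteopenia boundary
  a <- 1.5 / (c2 - c1)
  b <- -2.5 - a * c1
  a * bmd + b
}
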