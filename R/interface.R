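## Configuration, field sampling/export, cross-validation and fixture
## generation.  Output units are always the reduced units (lengths in a,
## velocities in a*Omega, pressure in Omega*nu3/a, resistance in nu3*a^2).

#' Read a run configuration from YAML or JSON
#'
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be .yaml/.yml or .json")
}

#' Build a disk problem from a configuration list
#'
#' Accepts either the dimensionless block `{A, b, beta, c}` or the physical
#' block `{nu1..nu5, m_par_sq, m_perp_sq, a, Omega}`.
#'
#' @param cfg Named list (e.g. from [read_config()]).
#' @return A `"disk_problem"`.
#' @export
problem_from_config <- function(cfg) {
  if (!is.null(cfg$nu1)) {
    fl <- fluid_params(cfg$nu1, cfg$nu2, cfg$nu3, cfg$nu4, cfg$nu5)
    fr <- friction_from_m(cfg$m_par_sq %||% 0, cfg$m_perp_sq %||% 0, cfg$nu3)
    disk_problem(fl, fr, a = cfg$a %||% 1, Omega = cfg$Omega %||% 1)
  } else {
    fl <- fluid_from_anisotropies(cfg$A %||% 0, cfg$b %||% 0)
    cc <- cfg$c %||% 0
    beta <- cfg$beta %||% 0
    fr <- if (cc == 0) friction_from_alphas(0, 0)
          else friction_from_alphas(cc, cc * (1 - beta))
    disk_problem(fl, fr, a = 1, Omega = 1)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample hydrodynamic fields on a polar grid
#'
#' Evaluates velocity and pressure on a polar grid (log-spaced radii from
#' the rim outward, uniform angles) and attaches the correction columns
#' `v_rho_star`, `v_theta_star`, `p_star`: the field minus the isotropic
#' base solution, the quantity the anisotropy acts on.
#'
#' @param problem A `"disk_problem"`.
#' @param method `"auto"` (exact series when frictionless and `A >= 0`,
#'   spectral otherwise), `"exact"`, `"ies"` or `"oracle"`.
#' @param n_rho,n_theta Grid size (both `>= 2`).
#' @param rho_max Outer radius in units of `a` (`> 1`).
#' @param sol Optional pre-computed `"oracle_solution"` to reuse.
#' @return A data frame (`FieldTable`) with columns `rho`, `theta`,
#'   `v_rho`, `v_theta`, `p`, `v_rho_star`, `v_theta_star`, `p_star`.
#' @export
sample_fields <- function(problem, method = c("auto", "exact", "ies", "oracle"),
                          n_rho = 16, n_theta = 16, rho_max = 5, sol = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(problem, "disk_problem"), rho_max > 1, n_rho >= 2, n_theta >= 2)
  A <- problem$fluid$A
  frictionless <- problem$friction$frictionless
  if (method == "auto")
    method <- if (frictionless && A >= 0) "exact" else if (A == 0 &&
      !frictionless && identical(problem$beta, 0) && problem$fluid$b == 0)
      "ies" else "oracle"
  rho <- exp(seq(0, log(rho_max), length.out = n_rho))
  theta <- 2 * pi * (0:(n_theta - 1)) / n_theta
  gr <- expand.grid(rho = rho, theta = theta, KEEP.OUT.ATTRS = FALSE)
  base_vtheta <- if (frictionless) 1 / gr$rho else {
    ies_velocity(problem$c * gr$rho, problem$c)$v_theta
  }
  if (method == "exact") {
    v <- exact_velocity(gr$rho, gr$theta, problem)
    p <- exact_pressure(gr$rho, gr$theta, problem)$p
  } else if (method == "ies") {
    if (frictionless) stop("method 'ies' requires friction (c > 0)")
    v <- data.frame(v_rho = 0 * gr$rho, v_theta = base_vtheta)
    p <- base_pressure_correction(problem$c * gr$rho, gr$theta,
                                  problem$c, problem$fluid$b)
  } else {
    if (is.null(sol)) sol <- oracle_solve(problem, resistance = FALSE)
    v <- oracle_velocity(gr$rho, gr$theta, sol)
    p <- oracle_pressure(gr$rho, gr$theta, sol)$p
  }
  data.frame(rho = gr$rho, theta = gr$theta,
             v_rho = v$v_rho, v_theta = v$v_theta, p = p,
             v_rho_star = v$v_rho,
             v_theta_star = v$v_theta - base_vtheta,
             p_star = p)
}

#' Pointwise correction field
#'
#' Subtracts a base field table from a full one on the same grid; used to
#' isolate the anisotropy-induced part of the flow.
#'
#' @param full,base Field tables from [sample_fields()] on identical grids.
#' @return A field table of differences (the `*_star` columns equal the
#'   value columns).
#' @export
correction_field <- function(full, base) {
  if (nrow(full) != nrow(base) ||
      max(abs(full$rho - base$rho), abs(full$theta - base$theta)) > 1e-12)
    stop("field tables are on different grids")
  out <- full
  for (cl in c("v_rho", "v_theta", "p")) {
    out[[cl]] <- full[[cl]] - base[[cl]]
    out[[paste0(cl, "_star")]] <- out[[cl]]
  }
  out
}

#' Write a field table as CSV with a JSON sidecar
#'
#' Floats are written with 17 significant digits so that re-reading and
#' re-exporting is byte-identical.
#'
#' @param ft Field table.
#' @param path Output CSV path; the sidecar goes to `<path>.json`.
#' @param meta Named list of provenance entries for the sidecar.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(ft, path, meta = list()) {
  fmt <- vapply(ft, function(cl)
    if (is.double(cl)) sprintf("%.17g", cl + 0) else as.character(cl),
    character(nrow(ft)))
  fmt <- matrix(fmt, nrow = nrow(ft))
  con <- file(path, "wb")
  writeLines(paste(names(ft), collapse = ","), con)
  writeLines(apply(fmt, 1, paste, collapse = ","), con)
  close(con)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run a configured computation
#'
#' Dispatch on `config$mode`:
#' \describe{
#'   \item{`mobility`}{resistance/mobility report, written as JSON.}
#'   \item{`fields-exact`, `fields-ies`, `oracle`}{field table on the
#'     configured grid, written as CSV plus sidecar.}
#'   \item{`validate`}{cross-check sweep (exact vs spectral vs
#'     perturbative) with a pass/fail table.}
#' }
#'
#' @param config Named list (see [read_config()]): parameters plus
#'   optionally `grid = list(n_rho, n_theta, rho_max)`, `out` (output file
#'   stem) and `seed` (validate mode only).
#' @param out_dir Output directory (default `"."`).
#' @return The computed object, invisibly (report, field table, or
#'   validation table).
#' @export
run_config <- function(config, out_dir = ".") {
  mode <- config$mode %||% stop("config$mode is required")
  pr <- problem_from_config(config)
  out_name <- config$out %||% mode
  stem <- if (grepl("^(/|[A-Za-z]:)", out_name)) out_name
          else file.path(out_dir, out_name)
  meta <- list(mode = mode, A = pr$fluid$A, b = pr$fluid$b,
               beta = pr$beta, c = pr$c, units = "reduced")
  if (mode == "mobility") {
    rep <- mobility(pr$fluid$A, if (is.na(pr$beta)) 0 else pr$beta, pr$c)
    jsonlite::write_json(unclass(rep), paste0(stem, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(rep))
  }
  if (mode %in% c("fields-exact", "fields-ies", "oracle")) {
    g <- config$grid %||% list()
    method <- c("fields-exact" = "exact", "fields-ies" = "ies",
                "oracle" = "oracle")[[mode]]
    sol <- NULL
    if (method == "oracle") {
      sol <- oracle_solve(pr, N_quad = config$n_quad %||% 256,
                          tol = config$tol %||% 1e-8)
      if (!sol$converged) stop("spectral solution did not converge")
      meta$N_modes <- sol$N_modes; meta$N_quad <- sol$N_quad
      meta$bc_residual <- sol$bc_residual
    }
    ft <- sample_fields(pr, method, n_rho = g$n_rho %||% 16,
                        n_theta = g$n_theta %||% 16,
                        rho_max = g$rho_max %||% 5, sol = sol)
    write_field_csv(ft, paste0(stem, ".csv"), meta)
    return(invisible(ft))
  }
  if (mode == "validate") {
    seed <- config$seed %||% 1
    tab <- validate_crosschecks(seed = seed)
    message("validation seed: ", seed)
    print(tab)
    jsonlite::write_json(tab, paste0(stem, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    return(invisible(tab))
  }
  stop("unknown mode: ", mode)
}

#' Cross-check sweep between the three solution tiers
#'
#' Runs a small randomized battery comparing the exact zero-friction
#' series, the perturbative expansion and the spectral solver against one
#' another, and reports each check with its discrepancy.
#'
#' @param seed Seed for the randomized parameter draws.
#' @return Data frame with columns `check`, `value`, `reference`,
#'   `discrepancy`, `pass`.
#' @export
validate_crosschecks <- function(seed = 1) {
  set.seed(seed)
  rows <- list()
  add <- function(check, value, reference, tol) {
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, value = value, reference = reference,
      discrepancy = abs(value - reference), pass = abs(value - reference) < tol)
  }
  add("exact resistance, isotropic limit", exact_resistance(0), 4 * pi, 1e-12)
  cs <- stats::runif(5, 0.05, 20)
  add("base resistance vs scaled classical form",
      max(abs(vapply(cs, resistance_ies, 0) -
                4 * pi * vapply(cs, evans_sackmann_rotational, 0))), 0, 1e-10)
  A <- stats::runif(1, 1, 5)
  pr <- suppressWarnings(disk_problem(fluid_from_anisotropies(A)))
  sol <- oracle_solve(pr)
  add(sprintf("spectral vs exact resistance (A = %.3f)", A),
      as.numeric(sol$R_numeric), exact_resistance(A), 1e-6)
  eps <- 0.1
  pre <- disk_problem(fluid_from_anisotropies(eps),
                      friction_from_alphas(1, 1 - eps))
  sole <- oracle_solve(pre)
  add("spectral vs perturbative resistance (A = beta = 0.1, c = 1)",
      as.numeric(sole$R_numeric), mobility(eps, eps, 1)$R_total, 5e-3)
  th <- stats::runif(1, 0, 2 * pi)
  add(sprintf("spectral vs closed-form rim pressure (A = %.3f)", A),
      oracle_pressure(1, th, sol)$p, rim_pressure(th, A, 0), 5e-5)
  do.call(rbind, rows)
}

#' Generate golden fixtures
#'
#' Writes deterministic fixture files: the principal-part polynomials of
#' the low-order Laurent table, the second-order Taylor polynomials of the
#' exact frictionless modes sampled on a `w` grid, and a perturbative
#' resistance sweep over the scaled friction `c`.
#'
#' @param dir Output directory.
#' @param seed Recorded in the outputs; the fixtures are fully
#'   deterministic given it.
#' @return Invisibly, the vector of files written.
#' @export
generate_fixtures <- function(dir, seed = 1) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # principal parts, n = 0..4, m = n+1..n+3
  pps <- list()
  for (n in 0:4) for (m in (n + 1):(n + 3)) {
    pp <- principal_part(m, n)
    pps[[sprintf("m%d_n%d", m, n)]] <- pp$terms
  }
  f1 <- file.path(dir, "principal_parts.json")
  jsonlite::write_json(pps, f1, digits = NA, pretty = TRUE)
  # second-order A-expansions of the exact modes on a w grid
  wgrid <- seq(0.1, 1, by = 0.1)
  rows <- list()
  modes <- list(
    g2 = function(Ac, w) exact_mode_g(2, w, Ac),
    g4 = function(Ac, w) exact_mode_g(4, w, Ac),
    h2 = function(Ac, w) exact_mode_h(2, w, Ac),
    h4 = function(Ac, w) exact_mode_h(4, w, Ac)
  )
  for (n in 1:5)
    modes[[paste0("u", n)]] <- local({
      nn <- n
      function(Ac, w) exact_mode_u(nn, w, Ac, b = 1)
    })
  for (nm in names(modes)) for (w in wgrid) {
    cf <- .taylor_in_A(function(Ac) as.complex(modes[[nm]](Ac, w)), 2)
    rows[[length(rows) + 1L]] <- data.frame(
      mode = nm, w = w, order0 = cf[1], order1 = cf[2], order2 = cf[3])
  }
  f2 <- file.path(dir, "mode_expansions.csv")
  write_field_csv(do.call(rbind, rows), f2,
                  list(seed = seed, b = 1, content = "Taylor in A, order 2"))
  # resistance sweep
  cc <- exp(seq(log(0.01), log(100), length.out = 25))
  sw <- list()
  for (ab in list(c(0, 0), c(0.5, 0), c(0, 0.5), c(0.5, 0.5))) {
    R <- vapply(cc, function(ci) mobility(ab[1], ab[2], ci)$R_total, 0)
    sw[[length(sw) + 1L]] <- data.frame(A = ab[1], beta = ab[2], c = cc, R_total = R)
  }
  f3 <- file.path(dir, "resistance_sweep.csv")
  write_field_csv(do.call(rbind, sw), f3, list(seed = seed))
  invisible(c(f1, f2, f3))
}
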