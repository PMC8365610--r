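# ---- run configuration -----------------------------------------------------

# allowed keys per config block; anything else is rejected so typos fail fast
config_schema <- list(
  top = c("model", "architecture", "protocol", "output", "seed",
          "tolerances"),
  model = c("framework", "passive", "W1", "W2", "active", "Fa"),
  passive = c("form", "mu", "c10", "c01", "c1", "c2", "tension_only"),
  active = c("type", "P_max", "alpha", "population"),
  population = c("source", "attachment_fraction", "N_xb", "distribution",
                 "x0", "x_lo", "x_hi", "x_pre", "x_post", "post_fraction",
                 "csv", "k_xb", "phi", "A_f_ref", "A_xf_ref"),
  Fa = c("form", "lambda_a_min", "gamma_a_max", "direction_index"),
  architecture = c("a0f", "e2", "e3", "phi_lattice"),
  protocol = c("kind", "lambda_range", "gamma_range", "n_steps", "alpha",
               "alpha_ramp", "lambda_f_rate"),
  output = c("units", "path"),
  tolerances = c("tol_J"))

check_keys <- function(block, allowed, where) {
  if (is.null(block)) return(invisible(NULL))
  unknown <- setdiff(names(block), allowed)
  if (length(unknown))
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  invisible(NULL)
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON — YAML is a superset) run configuration, validates
#' it strictly (unknown keys anywhere are rejected), and returns a
#' `run_config` object. The configuration fully determines a simulation:
#' constitutive model, fiber architecture, loading protocol, output options
#' and the seed, so loading the same file twice gives identical runs.
#'
#' @param path path to the YAML configuration file.
#' @return object of class `run_config` (validated nested list).
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' Validate a run-configuration list
#'
#' @param cfg nested list as produced by [load_run_config()] or built in R.
#' @return the validated `run_config` object.
#' @export
validate_run_config <- function(cfg) {
  if (!is.list(cfg)) stop("config must be a mapping", call. = FALSE)
  check_keys(cfg, config_schema$top, "config")
  if (is.null(cfg$model$framework))
    stop("config: model.framework is required", call. = FALSE)
  check_keys(cfg$model, config_schema$model, "model")
  for (blk in c("passive", "W1", "W2"))
    check_keys(cfg$model[[blk]], config_schema$passive,
               paste0("model.", blk))
  check_keys(cfg$model$active, config_schema$active, "model.active")
  check_keys(cfg$model$active$population, config_schema$population,
             "model.active.population")
  check_keys(cfg$model$Fa, config_schema$Fa, "model.Fa")
  check_keys(cfg$architecture, config_schema$architecture, "architecture")
  check_keys(cfg$protocol, config_schema$protocol, "protocol")
  check_keys(cfg$output, config_schema$output, "output")
  check_keys(cfg$tolerances, config_schema$tolerances, "tolerances")
  if (!is.null(cfg$output$units) &&
      !cfg$output$units %in% c("Pa", "N/cm^2"))
    stop("output.units must be 'Pa' or 'N/cm^2'", call. = FALSE)
  # constructing the objects performs the remaining domain validation
  arch <- config_architecture(cfg)
  config_model(cfg)
  config_protocol(cfg)
  structure(cfg, class = "run_config")
}

#' Serialize a run configuration to YAML
#'
#' A loaded configuration round-trips: `load -> dump -> load` yields an
#' identical model.
#'
#' @param cfg a `run_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
dump_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_architecture <- function(cfg) {
  a <- cfg$architecture
  if (is.null(a)) a <- list()
  fiber_architecture(
    a0f = if (is.null(a$a0f)) c(1, 0, 0) else unlist(a$a0f),
    e2 = if (is.null(a$e2)) NULL else unlist(a$e2),
    e3 = if (is.null(a$e3)) NULL else unlist(a$e3),
    phi_lattice = if (is.null(a$phi_lattice)) 0 else a$phi_lattice)
}

config_passive <- function(blk) {
  if (is.null(blk)) return(NULL)
  if (is.null(blk$form)) stop("passive block needs a 'form'", call. = FALSE)
  pars <- blk[setdiff(names(blk), c("form", "tension_only"))]
  do.call(passive_model,
          c(list(form = blk$form), pars,
            list(tension_only = if (is.null(blk$tension_only)) TRUE
                 else isTRUE(blk$tension_only))))
}

config_active_source <- function(blk, seed = 1L) {
  if (is.null(blk) || identical(blk$type, "none")) return(NULL)
  if (identical(blk$type, "phenomenological")) {
    return(phen_active_state(
      P_max = if (is.null(blk$P_max)) 25e4 else blk$P_max,
      alpha = if (is.null(blk$alpha)) 1 else blk$alpha))
  }
  if (identical(blk$type, "crossbridge")) {
    pb <- blk$population
    if (is.null(pb)) pb <- list(source = "default")
    src <- if (is.null(pb$source)) "default" else pb$source
    geom <- default_xb_parameters()
    for (nm in c("k_xb", "phi", "A_f_ref", "A_xf_ref"))
      if (!is.null(pb[[nm]])) geom[[nm]] <- pb[[nm]]
    af <- if (is.null(pb$attachment_fraction)) 1 else pb$attachment_fraction
    if (src == "default") {
      pop <- default_crossbridge_population(af)
      for (nm in c("k_xb", "phi", "A_f_ref", "A_xf_ref"))
        if (!is.null(pb[[nm]])) pop[[nm]] <- pb[[nm]]
      return(pop)
    }
    if (src == "csv") {
      if (is.null(pb$csv)) stop("population.csv path required",
                                call. = FALSE)
      x <- read_elongations_csv(pb$csv)
      return(crossbridge_population(geom$k_xb, x, geom$phi, geom$A_f_ref,
                                    geom$A_xf_ref))
    }
    if (src == "spec") {
      spec <- population_spec(
        N_xb = if (is.null(pb$N_xb)) geom$N_xb else pb$N_xb,
        attachment_fraction = af,
        x_distribution = if (is.null(pb$distribution)) "point-mass"
                         else pb$distribution,
        x0 = if (is.null(pb$x0)) geom$x0 else pb$x0,
        x_lo = if (is.null(pb$x_lo)) 0 else pb$x_lo,
        x_hi = if (is.null(pb$x_hi)) 8e-9 else pb$x_hi,
        x_pre = if (is.null(pb$x_pre)) 0 else pb$x_pre,
        x_post = if (is.null(pb$x_post)) geom$x0 else pb$x_post,
        post_fraction = if (is.null(pb$post_fraction)) 0.7
                        else pb$post_fraction,
        seed = seed)
      return(generate_population(spec, geom$k_xb, geom$phi, geom$A_f_ref,
                                 geom$A_xf_ref))
    }
    stop("unknown population source: ", src, call. = FALSE)
  }
  stop("unknown active source type: ", blk$type, call. = FALSE)
}

config_Fa_rule <- function(blk) {
  if (is.null(blk) || is.null(blk$form)) return(make_Fa_rule("identity"))
  make_Fa_rule(
    form = blk$form,
    lambda_a_min = if (is.null(blk$lambda_a_min)) 0.7 else blk$lambda_a_min,
    gamma_a_max = if (is.null(blk$gamma_a_max)) 0.3 else blk$gamma_a_max,
    direction_index = if (is.null(blk$direction_index)) 2L
                      else as.integer(blk$direction_index))
}

config_model <- function(cfg) {
  m <- cfg$model
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  muscle_model(
    framework = m$framework,
    passive = config_passive(m$passive),
    W1 = config_passive(m$W1),
    W2 = config_passive(m$W2),
    active_source = config_active_source(m$active, seed),
    Fa_rule = config_Fa_rule(m$Fa))
}

config_protocol <- function(cfg) {
  p <- cfg$protocol
  if (is.null(p) || is.null(p$kind))
    stop("config: protocol.kind is required", call. = FALSE)
  alpha <- if (!is.null(p$alpha_ramp)) {
    rng <- unlist(p$alpha_ramp)
    function(s) rng[1L] + s * (rng[2L] - rng[1L])
  } else if (is.null(p$alpha)) 0 else p$alpha
  loading_protocol(
    kind = p$kind,
    lambda_range = if (is.null(p$lambda_range)) c(1, 1.2)
                   else unlist(p$lambda_range),
    gamma_range = if (is.null(p$gamma_range)) c(0, 0.4)
                  else unlist(p$gamma_range),
    n_steps = if (is.null(p$n_steps)) 11L else p$n_steps,
    alpha_schedule = alpha,
    lambda_f_rate = if (is.null(p$lambda_f_rate)) 0 else p$lambda_f_rate)
}

# ---- command-line operations ----------------------------------------------

#' Run a configured simulation and write its outputs
#'
#' Loads a run configuration, executes the loading protocol against the
#' configured constitutive model, and writes (atomically) the result table
#' as CSV — prefixed by a `#` units header line — plus a JSON run manifest
#' (config MD5, package version, seed). Stresses are written in the
#' configured units (`Pa` or `N/cm^2`; 1 N cm^-2 = 1e4 Pa).
#'
#' @param config_path YAML configuration path.
#' @param out_csv output CSV path; default: `output.path` from the config,
#'   falling back to `"results.csv"`.
#' @return invisibly, a list with `table` (the result data.frame in output
#'   units), `csv` and `manifest` paths.
#' @export
cli_simulate <- function(config_path, out_csv = NULL) {
  cfg <- load_run_config(config_path)
  arch <- config_architecture(cfg)
  model <- config_model(cfg)
  protocol <- config_protocol(cfg)

  tab <- run_protocol(protocol, model, arch)

  units <- if (is.null(cfg$output$units)) "Pa" else cfg$output$units
  if (units == "N/cm^2") {
    stress_cols <- grep("^(P_|sigma_|branch_)|^p$", names(tab))
    tab[stress_cols] <- tab[stress_cols] / 1e4
  }
  if (is.null(out_csv))
    out_csv <- if (is.null(cfg$output$path)) "results.csv" else
      cfg$output$path

  # atomic write: stage in tempfiles, rename into place on success
  tmp <- tempfile(fileext = ".csv")
  con <- file(tmp, "w")
  writeLines(sprintf("# stress units: %s; one row per protocol step", units),
             con)
  utils::write.csv(tab, con, row.names = FALSE)
  close(con)
  if (!suppressWarnings(file.rename(tmp, out_csv))) {
    file.copy(tmp, out_csv, overwrite = TRUE)
    unlink(tmp)
  }

  manifest_path <- paste0(tools::file_path_sans_ext(out_csv),
                          "_manifest.json")
  manifest <- list(
    config = normalizePath(config_path),
    config_md5 = unname(tools::md5sum(config_path)),
    package = "musclemech",
    version = as.character(utils::packageVersion("musclemech")),
    seed = if (is.null(cfg$seed)) 1L else cfg$seed,
    units = units,
    n_steps = nrow(tab))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(table = tab, csv = out_csv, manifest = manifest_path))
}

#' Verify the package's structural identities
#'
#' Recomputes the algebraic identities the constitutive frameworks rely on
#' and prints a pass/fail table with the maximum observed residual for each:
#' the hexagonal lattice identity `sum t_n %o% t_n = 3 (I - M)`,
#' unimodularity of both active deformation gradient forms, the reduction of
#' every framework to the passive stress at zero activation, and agreement
#' of every analytic stress with the finite-difference oracle.
#'
#' @param quiet suppress the printed table.
#' @param perturb internal test hook: name of an identity
#'   (`"lattice"`) whose computation is deliberately perturbed to verify the
#'   harness detects failures.
#' @return invisibly, integer exit status: 0 if all identities hold, 1
#'   otherwise. The checks data.frame is attached as attribute `"report"`.
#' @export
cli_verify <- function(quiet = FALSE, perturb = NULL) {
  checks <- list()
  add <- function(name, residual, tol)
    checks[[length(checks) + 1L]] <<- data.frame(
      identity = name, max_residual = residual, tolerance = tol,
      pass = residual <= tol)

  # lattice identity over random architectures
  res <- 0
  for (s in 1:50) {
    Q <- random_rotation(s)
    arch <- fiber_architecture(Q %*% c(1, 0, 0), phi_lattice = s * 0.12)
    tn <- crossfiber_directions(arch)
    lhs <- tcrossprod(tn)
    if (identical(perturb, "lattice")) lhs <- lhs + 1e-6
    res <- max(res, max(abs(lhs - 3 * (diag(3) -
                                       structural_tensor(arch)))))
  }
  add("sum(t_n x t_n) = 3(I - a0f x a0f)", res, 1e-12)

  arch <- fiber_architecture(c(1, 0, 0))
  res <- 0
  for (la in c(0.5, 0.7, 0.9, 1.1, 1.3))
    res <- max(res, abs(det(build_Fa_fiber_contraction(la, arch)) - 1))
  for (ga in seq(-0.5, 0.5, by = 0.1))
    res <- max(res, abs(det(build_Fa_shear(ga, arch)) - 1))
  add("det(Fa) = 1 (both forms)", res, 1e-12)

  # zero-activation reductions to the passive stress
  nh <- passive_model("neo-hookean", mu = 1e4)
  res <- 0
  for (s in 1:10) {
    F <- random_isochoric_F(s)
    p0 <- 5e3
    Pp <- pk1_incompressible(F, p0, arch, nh)$P
    Pas <- additive_total_stress(F, p0, arch, nh, NULL)$P
    Pst <- active_strain_stress(F, p0, arch, nh, diag(3))$P
    Pmx <- mixed_stress(F, p0, arch,
                        mixed_model_config(W1_model = nh), alpha = 0)$P
    res <- max(res, max(abs(Pas - Pp)), max(abs(Pst - Pp)),
               max(abs(Pmx - Pp)))
  }
  add("zero-activation reduction to passive stress", res, 1e-12 * 1e4)

  # analytic stress vs finite-difference oracle
  fr <- passive_model("fiber-reinforced", mu = 5e3, c1 = 2e3, c2 = 1.5)
  res <- 0
  for (s in 1:20) {
    F <- random_isochoric_F(s + 100)
    for (model in list(nh, fr)) {
      Pa <- pk1_incompressible(F, 1e3, arch, model)$P
      Pfd <- fd_stress_oracle(F, 1e3, arch, model)
      res <- max(res, max(abs(Pa - Pfd)) / max(abs(Pa), 1))
    }
  }
  add("analytic stress = FD oracle (relative)", res, 1e-5)

  report <- do.call(rbind, checks)
  if (!quiet) {
    cat("musclemech structural identity checks\n")
    print(transform(report,
                    max_residual = signif(max_residual, 3),
                    status = ifelse(pass, "PASS", "FAIL")),
          row.names = FALSE)
  }
  status <- if (all(report$pass)) 0L else 1L
  invisible(structure(status, report = report))
}
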