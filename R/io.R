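#' Load model parameters from a file
#'
#' Reads a YAML or JSON key-value file with any of the keys `delta`, `a`,
#' `b`, `kappa`, `gamma`, `lambda` (or `lam`); missing keys are filled from
#' the default parameter set with a message. Validation errors name the
#' offending key.
#'
#' @param path file path (`.json`, `.yaml`/`.yml`; anything else is parsed
#'   as YAML).
#' @return A [model_params()] object.
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(vals)) vals <- list()
  if (!is.null(vals[["lambda"]]) && is.null(vals[["lam"]]))
    vals[["lam"]] <- vals[["lambda"]]
  defaults <- formals(model_params)
  keys <- c("delta", "a", "b", "kappa", "gamma", "lam")
  args <- list()
  for (k in keys) {
    if (!is.null(vals[[k, exact = TRUE]])) {
      args[[k]] <- vals[[k]]
    } else {
      args[[k]] <- eval(defaults[[k]])
      message("load_params: '", k, "' missing, using default ", args[[k]])
    }
  }
  unknown <- setdiff(names(vals), c(keys, "lambda"))
  if (length(unknown))
    message("load_params: ignoring unknown keys: ",
            paste(unknown, collapse = ", "))
  do.call(model_params, args)
}

#' Write / read a travelling-wave profile as CSV
#'
#' Profiles are stored as plain CSV with header `xi,M,S,omega` at full
#' float precision (17 significant digits), so that a write/read round
#' trip reproduces the arrays exactly. On read, the header is validated,
#' non-finite values are rejected, and `xi` must be strictly increasing
#' (violations are reported with their line number).
#'
#' @param profile a `tw_profile`.
#' @param path output / input file path.
#' @return `write_profile` returns `path` invisibly; `read_profile`
#'   returns a `tw_profile` (with `v` and `omega_inf` set to `NA` unless
#'   recoverable from context).
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "tw_profile"))
  df <- data.frame(xi = profile$xi, M = profile$M, S = profile$S,
                   omega = profile$omega)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("xi,M,S,omega", con)
  writeLines(paste(format(df$xi, digits = 17, scientific = TRUE, trim = TRUE),
                   format(df$M, digits = 17, scientific = TRUE, trim = TRUE),
                   format(df$S, digits = 17, scientific = TRUE, trim = TRUE),
                   format(df$omega, digits = 17, scientific = TRUE, trim = TRUE),
                   sep = ","), con)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2) stop("empty or header-only profile file: ", path)
  if (!identical(trimws(lines[1]), "xi,M,S,omega"))
    stop("malformed profile header (expected 'xi,M,S,omega'): ", path)
  df <- utils::read.csv(text = lines, header = TRUE)
  if (!all(c("xi", "M", "S", "omega") %in% names(df)))
    stop("malformed profile columns in ", path)
  bad <- which(!stats::complete.cases(df) |
                 !apply(as.matrix(df), 1, function(r) all(is.finite(r))))
  if (length(bad))
    stop("non-finite profile values at line ", bad[1] + 1L, " of ", path)
  nonmono <- which(diff(df$xi) <= 0)
  if (length(nonmono))
    stop("xi not strictly increasing at line ", nonmono[1] + 2L, " of ", path)
  structure(list(xi = df$xi, M = df$M, S = df$S, omega = df$omega,
                 v = NA_real_, omega_inf = NA_real_),
            class = "tw_profile")
}

#' L1 discrepancy of two wave profiles up to translation
#'
#' Travelling waves are translation-invariant, so profiles from different
#' solvers are compared after aligning them: the biomass curves are
#' interpolated onto a common grid and the shift `c` minimising
#' \eqn{\int |M_a(\xi) - M_b(\xi - c)|\, d\xi} is found by a coarse scan
#' refined with golden-section search.
#'
#' @param a,b `tw_profile` objects.
#' @param shift maximum allowed translation (default: the combined support
#'   width, which always admits an overlap).
#' @return A list with `l1` (minimised discrepancy), `shift` (optimal
#'   translation of `b`), and `l1_relative` (`l1` divided by the biomass
#'   mass of `a`).
#' @export
compare_profiles <- function(a, b, shift = NULL) {
  stopifnot(inherits(a, "tw_profile"), inherits(b, "tw_profile"))
  span_a <- diff(range(a$xi)); span_b <- diff(range(b$xi))
  if (is.null(shift)) shift <- span_a + span_b
  centre <- function(pr) {
    w <- pr$M / max(sum(pr$M), .Machine$double.eps)
    sum(pr$xi * w)
  }
  c0 <- centre(a) - centre(b)
  if (abs(c0) - shift > (span_a + span_b) / 2)
    stop("profiles have disjoint supports within the allowed translation")
  grid <- seq(min(a$xi), max(a$xi), length.out = 2048)
  fa <- stats::approxfun(a$xi, a$M, yleft = NA, yright = NA)
  fb <- stats::approxfun(b$xi, b$M, yleft = NA, yright = NA)
  Ma <- fa(grid)
  obj <- function(cc) {
    Mb <- fb(grid - cc)
    ok <- !is.na(Ma) & !is.na(Mb)
    if (sum(ok) < 10) return(Inf)
    # integrate |diff| over the overlap, extending by the tails cut off
    mean_dx <- diff(grid[1:2])
    sum(abs(Ma[ok] - Mb[ok])) * mean_dx
  }
  cand <- seq(c0 - shift, c0 + shift, length.out = 201)
  vals <- vapply(cand, obj, numeric(1))
  if (!any(is.finite(vals)))
    stop("profiles have disjoint supports within the allowed translation")
  i <- which.min(vals)
  lo <- cand[max(1, i - 1)]; hi <- cand[min(length(cand), i + 1)]
  opt <- stats::optimize(obj, c(lo, hi))
  mass_a <- sum(a$M[-1] * diff(a$xi))
  list(l1 = opt$objective, shift = opt$minimum,
       l1_relative = opt$objective / mass_a)
}

#' Serialise an existence report to JSON
#'
#' @param x an [existence_report()] object.
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "existence_report"))
  lst <- unclass(x)
  lst$params <- unclass(lst$params)
  js <- jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Write a run manifest
#'
#' Records the command, parameter set, configuration, package version and
#' output inventory of a command-line run as JSON, so that a run can be
#' reproduced exactly from its manifest (the solvers are deterministic).
#'
#' @param command command name.
#' @param params a [model_params()] object.
#' @param config a solver or simulation configuration (or `NULL`).
#' @param outputs character vector of files written.
#' @param path manifest path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(command, params, config, outputs, path) {
  man <- list(command = command,
              package = "biofilmTW",
              version = as.character(utils::packageVersion("biofilmTW")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              params = unclass(params),
              config = if (is.null(config)) NULL else unclass(config),
              outputs = outputs)
  writeLines(jsonlite::toJSON(man, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
  invisible(path)
}
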