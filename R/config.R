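# Configuration I/O and fixture generation.

.fixture_table <- list(
  hopf1 = list(alpha = 1, d = 0, tau0 = 0.75, gamma = 3.3482,
               kernel = list(list(eta = 12.5, mu = 2),
                             list(eta = -10, mu = 1))),
  hopf2 = list(alpha = 1, d = 0.2, tau0 = 0.75, gamma = 3.3094,
               kernel = list(list(eta = 12.5, mu = 2),
                             list(eta = -10, mu = 1)))
)

config_to_model <- function(cfg, where = "config") {
  required <- c("alpha", "d", "tau0", "gamma", "kernel")
  missing_keys <- setdiff(required, names(cfg))
  if (length(missing_keys)) {
    stop(where, ": missing key(s): ", paste(missing_keys, collapse = ", "))
  }
  unknown <- setdiff(names(cfg), required)
  if (length(unknown)) {
    stop(where, ": unknown key(s): ", paste(unknown, collapse = ", "))
  }
  kern <- cfg$kernel
  if (is.data.frame(kern)) kern <- split(kern, seq_len(nrow(kern)))
  eta <- vapply(kern, function(k) {
    if (!all(sort(names(k)) == c("eta", "mu"))) {
      stop(where, ": each kernel term needs exactly the keys eta, mu")
    }
    as.numeric(k$eta)
  }, numeric(1))
  mu <- vapply(kern, function(k) as.numeric(k$mu), numeric(1))
  nf_model(alpha = as.numeric(cfg$alpha), d = as.numeric(cfg$d),
           tau0 = as.numeric(cfg$tau0), eta = eta, mu = mu,
           gamma = as.numeric(cfg$gamma))
}

#' Bundled reference fixtures
#'
#' The two Hopf-point parameter sets of the reference model (wizard-hat
#' kernel `25/2 e^{-2|x-x'|} - 10 e^{-|x-x'|}`, sigmoid activation,
#' `alpha = 1`, `tau0 = 3/4`): `"hopf1"` without diffusion
#' (`d = 0, gamma = 3.3482`) and `"hopf2"` with diffusion
#' (`d = 0.2, gamma = 3.3094`).
#'
#' @param name `"hopf1"` or `"hopf2"`.
#' @return an `nf_model`.
#' @export
#' @examples
#' nf_fixture("hopf1")
nf_fixture <- function(name = c("hopf1", "hopf2")) {
  name <- match.arg(name)
  config_to_model(.fixture_table[[name]], where = name)
}

#' Read a model from a configuration file
#'
#' YAML (`.yml`/`.yaml`) or JSON with keys `alpha`, `d`, `tau0`, `gamma` and
#' `kernel` (a list of `{eta, mu}` maps). Unknown keys are rejected. The
#' bundled fixture names (`"hopf1"`, `"hopf2"`) are also accepted in place
#' of a path.
#'
#' @param path file path or fixture name.
#' @return an `nf_model`.
#' @export
load_config <- function(path) {
  if (path %in% names(.fixture_table)) return(nf_fixture(path))
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  config_to_model(cfg, where = path)
}

#' Write a model to a canonical YAML configuration
#'
#' Keys are emitted in a fixed order so that load/save round-trips are
#' byte-identical for canonicalised configs. Only sigmoid-activation models
#' can be serialised.
#'
#' @param model an `nf_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(model, path) {
  stopifnot(inherits(model, "nf_model"))
  if (is.na(model$activation$gamma)) {
    stop("only sigmoid-activation models can be written to a config file")
  }
  cfg <- list(alpha = model$alpha, d = model$d, tau0 = model$tau0,
              gamma = model$activation$gamma,
              kernel = lapply(seq_len(model$N), function(j) {
                list(eta = model$eta[j], mu = model$mu[j])
              }))
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}

#' Random valid model fixtures for property tests
#'
#' Seeded generator of nondegenerate parameter sets:
#' `alpha in [0.5, 2]`, `d = 0` (one draw in three) or `d in [0.05, 0.5]`,
#' `tau0 in [0.25, 1]`, amplitudes `eta_j in [-15, 15]` bounded away from
#' zero (`|eta_j| >= 0.5`), and decay rates `mu_j` distinct in `[0.5, 4]`
#' with pairwise gap at least 0.2 (which keeps the `k_j^2 = k_p^2`
#' degeneracy away for every z). The gain is drawn in `[2, 4]`. The global
#' random-number state is left untouched.
#'
#' @param seed integer seed.
#' @param N number of kernel terms, 1 to 3.
#' @return an `nf_model`.
#' @export
random_fixture <- function(seed, N = 2L) {
  stopifnot(N %in% 1:3)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  alpha <- stats::runif(1, 0.5, 2)
  d <- if (stats::runif(1) < 1 / 3) 0 else stats::runif(1, 0.05, 0.5)
  tau0 <- stats::runif(1, 0.25, 1)
  eta <- numeric(N)
  for (j in seq_len(N)) {
    repeat {
      e <- stats::runif(1, -15, 15)
      if (abs(e) >= 0.5) break
    }
    eta[j] <- e
  }
  repeat {
    mu <- sort(stats::runif(N, 0.5, 4))
    if (N == 1L || min(diff(mu)) >= 0.2) break
  }
  gamma <- stats::runif(1, 2, 4)
  nf_model(alpha = alpha, d = d, tau0 = tau0, eta = eta, mu = mu,
           gamma = gamma)
}
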