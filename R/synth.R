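#' Difference-of-exponentials unit response kernel
#'
#' `k(t) = -peak * (exp(-t/tau_decay) - exp(-t/tau_rise)) / norm`, normalized
#' so the extremum equals `-peak` (inward currents are negative; `peak` is a
#' magnitude). The extremum is at
#' `t* = ln(tau_decay/tau_rise) * tau_rise * tau_decay / (tau_decay - tau_rise)`.
#'
#' @param tau_rise,tau_decay Rise and decay time constants (ms),
#'   `tau_decay > tau_rise > 0`.
#' @param peak Extremum magnitude (pA).
#' @param dt Sampling interval (ms).
#' @param t_end Kernel duration (ms); default `8 * tau_decay`.
#'
#' @return An `"ephys_trace"` starting at time 0.
#' @examples
#' k <- make_kernel(1, 5.75, peak = 10, dt = 0.1)
#' min(k$current)    # -10
#' @export
make_kernel <- function(tau_rise, tau_decay, peak = 1, dt = 0.1, t_end = NULL) {
  if (!(tau_decay > tau_rise && tau_rise > 0)) {
    stop("make_kernel: need tau_decay > tau_rise > 0", call. = FALSE)
  }
  if (is.null(t_end)) t_end <- 8 * tau_decay
  tt <- seq(0, t_end, by = dt)
  shape <- exp(-tt / tau_decay) - exp(-tt / tau_rise)
  tstar <- log(tau_decay / tau_rise) * tau_rise * tau_decay / (tau_decay - tau_rise)
  norm <- exp(-tstar / tau_decay) - exp(-tstar / tau_rise)
  new_trace(tibble::tibble(time = tt, current = -peak * shape / norm),
            unit = "pA", condition = "kernel")
}

#' Configuration of the synthetic-recording generator
#'
#' Describes a synthetic astrocyte recording: a fast transporter current
#' (biexponential kernel, decay ~5.75 ms for a single stimulus) riding on a
#' slow K+ current (decay hundreds of ms), evoked by a single stimulus or a
#' 5 x 50 Hz train, with per-stimulus facilitation factors, per-stimulus
#' decay-prolongation multipliers and additive Gaussian noise.
#'
#' @param protocol `"single"` or `"train"` (5 stimuli at 50 Hz).
#' @param iglut,ik Kernel settings: lists with `tau_rise`, `tau_decay` (ms)
#'   and `peak` (pA magnitude).
#' @param facilitation_iglut,facilitation_ik Per-stimulus amplitude factors
#'   (recycled to the number of stimuli).
#' @param tau_scale_iglut Per-stimulus multipliers of the transporter decay
#'   constant (use-dependent prolongation; last-response default ~4x the
#'   first, mirroring 23.65/5.75 ms).
#' @param noise_sd Gaussian noise SD (pA).
#' @param dt Sampling interval (ms), default 0.1 (10 kHz).
#' @param t_end Record length (ms).
#' @param t_stim First stimulus time (ms).
#' @param seed Mandatory integer seed.
#'
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(protocol = c("single", "train"),
                         iglut = list(tau_rise = 1, tau_decay = 5.75, peak = 10),
                         ik = list(tau_rise = 10, tau_decay = 300, peak = 30),
                         facilitation_iglut = c(1, 1.4, 1.8, 2.1, 2.3),
                         facilitation_ik = c(1, 1.8, 2.5, 3.1, 3.6),
                         tau_scale_iglut = c(1, 1.75, 2.5, 3.25, 4.11),
                         noise_sd = 1, dt = 0.1, t_end = 1200, t_stim = 50,
                         seed = NULL) {
  protocol <- match.arg(protocol)
  if (is.null(seed)) stop("synth_config: a seed is mandatory", call. = FALSE)
  for (kn in list(iglut, ik)) {
    stopifnot(kn$tau_decay > kn$tau_rise, kn$tau_rise > 0, kn$peak >= 0)
  }
  if (dt <= 0) stop("synth_config: dt must be > 0", call. = FALSE)
  if (any(facilitation_iglut <= 0) || any(facilitation_ik <= 0) ||
      any(tau_scale_iglut <= 0)) {
    stop("synth_config: factors must be > 0", call. = FALSE)
  }
  stim <- if (protocol == "single") t_stim else t_stim + 20 * (0:4)
  structure(list(protocol = protocol, iglut = iglut, ik = ik,
                 facilitation_iglut = facilitation_iglut,
                 facilitation_ik = facilitation_ik,
                 tau_scale_iglut = tau_scale_iglut,
                 noise_sd = noise_sd, dt = dt, t_end = t_end,
                 stim_times = stim, seed = as.integer(seed)),
            class = "synth_config")
}

# sum of shifted kernels over stimuli; component = "iglut" or "ik"
synth_component <- function(config, component) {
  kn <- config[[component]]
  stim <- config$stim_times
  fac <- rep_len(config[[paste0("facilitation_", component)]], length(stim))
  tsc <- if (component == "iglut") {
    rep_len(config$tau_scale_iglut, length(stim))
  } else {
    rep_len(1, length(stim))
  }
  tt <- seq(0, config$t_end, by = config$dt)
  y <- numeric(length(tt))
  for (i in seq_along(stim)) {
    kern <- make_kernel(kn$tau_rise, kn$tau_decay * tsc[i],
                        peak = kn$peak * fac[i], dt = config$dt,
                        t_end = config$t_end - stim[i])
    idx <- which(tt >= stim[i] - 1e-9)
    m <- min(length(idx), nrow(kern))
    y[idx[seq_len(m)]] <- y[idx[seq_len(m)]] + kern$current[seq_len(m)]
  }
  new_trace(tibble::tibble(time = tt, current = y), unit = "pA",
            stim_times = stim, condition = component)
}

#' Generate one synthetic combined recording with ground truth
#'
#' Builds the noise-free transporter and K+ components as sums of facilitated
#' (and, for the transporter, decay-prolonged) kernels, adds seeded Gaussian
#' noise, and returns everything: `combined = iglut + ik + noise` exactly.
#'
#' @param config A [synth_config()].
#'
#' @return A list of class `"synth_traces"`: `combined`, `iglut`, `ik`
#'   (traces), `noise` (numeric vector) and `config`.
#' @examples
#' st <- synth_trace(synth_config(protocol = "train", seed = 1))
#' @export
synth_trace <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  iglut <- synth_component(config, "iglut")
  ik <- synth_component(config, "ik")
  withr_seed <- config$seed
  noise <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(withr_seed)
    stats::rnorm(nrow(iglut), sd = config$noise_sd)
  })
  combined <- with_values(iglut, iglut$current + ik$current + noise,
                          condition = "combined")
  structure(list(combined = combined, iglut = iglut, ik = ik,
                 noise = noise, config = config),
            class = "synth_traces")
}

#' Generate a batch of paired (combined, K-only) synthetic cells
#'
#' Emulates per-cell recording pairs in which a transporter blocker isolates
#' the K+ current: for each cell the combined trace is generated with
#' cell-specific kernel parameters, and a K-only template is produced with the
#' transporter component zeroed and the K+ component rescaled by a per-cell
#' factor drawn from a seeded log-normal distribution (so the template
#' amplitude does not trivially match the combined tail).
#'
#' @param config A [synth_config()] serving as the base; per-cell jitter is
#'   applied to the transporter decay (+-15 %) and peaks (+-20 %).
#' @param n_cells Number of cells.
#' @param seed Batch seed (overrides `config$seed` as the randomness root).
#' @param dir Optional directory: when given, traces are written via
#'   [write_trace()] together with `manifest.json` (ground truth), and file
#'   paths are recorded in the manifest.
#'
#' @return A list of class `"synth_experiment"`: `cells` (list of per-cell
#'   lists with `combined`, `template`, `truth`), `manifest` (tibble of
#'   ground-truth parameters) and `config`.
#' @examples
#' ex <- synth_experiment(synth_config(seed = 1), n_cells = 2, seed = 7)
#' ex$manifest
#' @export
synth_experiment <- function(config, n_cells, seed, dir = NULL) {
  stopifnot(inherits(config, "synth_config"), n_cells >= 1)
  rng <- local({
    set.seed(as.integer(seed))
    list(tau = stats::runif(n_cells, 0.85, 1.15),
         pk_glut = stats::runif(n_cells, 0.8, 1.2),
         pk_k = stats::runif(n_cells, 0.8, 1.2),
         tboa_scale = stats::rlnorm(n_cells, log(1) - 0.5 * 0.15^2, 0.15),
         cell_seed = sample.int(1e6, 2 * n_cells))
  })
  cells <- vector("list", n_cells)
  rows <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    cfg <- config
    cfg$iglut$tau_decay <- config$iglut$tau_decay * rng$tau[i]
    cfg$iglut$peak <- config$iglut$peak * rng$pk_glut[i]
    cfg$ik$peak <- config$ik$peak * rng$pk_k[i]
    cfg$seed <- rng$cell_seed[2 * i - 1]
    st <- synth_trace(cfg)
    # K-only template: transporter zeroed, K rescaled, its own noise
    cfg_t <- cfg
    cfg_t$iglut$peak <- 0
    cfg_t$ik$peak <- cfg$ik$peak / rng$tboa_scale[i]
    cfg_t$seed <- rng$cell_seed[2 * i]
    tmpl <- synth_trace(cfg_t)$combined
    attr(tmpl, "condition") <- "tboa"
    truth <- tibble::tibble(
      cell = i,
      tau_decay = cfg$iglut$tau_decay,
      iglut_peak = cfg$iglut$peak,
      ik_peak = cfg$ik$peak,
      template_scale = rng$tboa_scale[i],
      noise_sd = cfg$noise_sd,
      facilitation = list(rep_len(cfg$facilitation_iglut,
                                  length(cfg$stim_times)))
    )
    cells[[i]] <- list(combined = st$combined, template = tmpl,
                       iglut = st$iglut, truth = truth)
    rows[[i]] <- truth
  }
  manifest <- dplyr::bind_rows(rows)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- purrr::imap(cells, function(cell, i) {
      pc <- file.path(dir, sprintf("cell%02d_combined.csv", i))
      pt <- file.path(dir, sprintf("cell%02d_tboa.csv", i))
      write_trace(cell$combined, pc)
      write_trace(cell$template, pt)
      list(combined = pc, tboa = pt)
    })
    manifest$combined_file <- purrr::map_chr(paths, "combined")
    manifest$tboa_file <- purrr::map_chr(paths, "tboa")
    mf <- manifest
    mf$facilitation <- purrr::map(mf$facilitation, identity)
    jsonlite::write_json(
      c(list(seed = as.integer(seed),
             base_config = config[setdiff(names(config), "stim_times")],
             stim_times = config$stim_times),
        list(cells = mf)),
      file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  structure(list(cells = cells, manifest = manifest, config = config,
                 seed = as.integer(seed)),
            class = "synth_experiment")
}
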