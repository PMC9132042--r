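#' Configuration for the reduced astrocyte morphology generator
#'
#' The reduced cell is a soma, straight primary branches split into cable
#' segments, and nanoscopic leaflet clusters attached along the branches.
#' A leaflet compartment represents `leaflet_cluster` identical leaflets in
#' parallel (areas, volumes and axial conductances scale with the cluster
#' size, which is exact for identical members).
#'
#' @param n_primary Number of primary branches.
#' @param branch_length Branch length (um); arbor radius ~ soma + this.
#' @param segments_per_branch Cable segments per branch.
#' @param soma_diameter Soma diameter (um).
#' @param taper Branch diameter at origin and tip (um).
#' @param leaflet_compartments Number of leaflet-cluster compartments.
#' @param leaflet_cluster Leaflets represented by one compartment.
#' @param leaflet_diameter,leaflet_length Uniform sampling ranges (um).
#' @param sv_target Acceptable surface-to-volume band (um^-1).
#' @param axial_resistivity Cytosolic resistivity (Ohm cm), default 150.
#' @param max_retry Retries (adjusting leaflet count) to satisfy `sv_target`.
#'
#' @return A list of class `"morphology_config"`.
#' @export
morphology_config <- function(n_primary = 6, branch_length = 40,
                              segments_per_branch = 5, soma_diameter = 10,
                              taper = c(1.2, 0.4),
                              leaflet_compartments = 280,
                              leaflet_cluster = 12,
                              leaflet_diameter = c(0.1, 0.3),
                              leaflet_length = c(1, 3),
                              sv_target = c(4, 16),
                              axial_resistivity = 150,
                              max_retry = 5) {
  stopifnot(n_primary >= 1, segments_per_branch >= 1, soma_diameter > 0,
            all(taper > 0), leaflet_compartments >= 0, leaflet_cluster >= 1,
            max(leaflet_diameter) < 1, sv_target[1] < sv_target[2],
            axial_resistivity > 0)
  structure(as.list(environment()), class = "morphology_config")
}

#' Build a reduced multi-compartment astrocyte
#'
#' Generates a statistically parameterised soma + branches + leaflets graph.
#' Deterministic for a given seed. Retries with an adjusted leaflet count if
#' the surface-to-volume ratio misses the configured band, and errors after
#' `max_retry` attempts.
#'
#' @param config A [morphology_config()].
#' @param seed Integer seed.
#'
#' @return A tibble of class `"astro_morphology"`, one row per compartment
#'   with columns `comp`, `class` (`soma`/`branch`/`leaflet`), `x`, `y`, `z`
#'   (um), `diameter`, `length` (um), `area` (um^2), `volume` (um^3),
#'   `n_units`, `parent`, `dist_soma` (um). Attributes: `edges` (tibble
#'   `from`, `to`, `g_axial` nS, `g_diff` um), `sv_ratio`, `config`, `seed`.
#' @examples
#' g <- build_reduced_morphology(morphology_config(leaflet_compartments = 40),
#'                               seed = 1)
#' attr(g, "sv_ratio")
#' @export
build_reduced_morphology <- function(config = morphology_config(), seed) {
  stopifnot(inherits(config, "morphology_config"))
  cfg <- config
  for (attempt in seq_len(config$max_retry)) {
    g <- with_seed(seed + (attempt - 1L), build_morphology_once(cfg))
    sv <- attr(g, "sv_ratio")
    if (sv >= config$sv_target[1] && sv <= config$sv_target[2]) {
      attr(g, "config") <- config
      attr(g, "seed") <- seed
      return(g)
    }
    # steer the leaflet count toward the band centre (leaflets dominate area)
    mid <- mean(config$sv_target)
    cfg$leaflet_compartments <-
      max(0L, as.integer(round(cfg$leaflet_compartments * mid / sv)))
  }
  stop("build_reduced_morphology: could not satisfy surface-to-volume target ",
       "band [", config$sv_target[1], ", ", config$sv_target[2], "] after ",
       config$max_retry, " attempts", call. = FALSE)
}

build_morphology_once <- function(cfg) {
  ra <- cfg$axial_resistivity * 1e4   # Ohm um
  seg_len <- cfg$branch_length / cfg$segments_per_branch
  soma_r <- cfg$soma_diameter / 2
  rows <- list()
  edges <- list()
  rows[[1]] <- tibble::tibble(
    comp = 1L, class = "soma", x = 0, y = 0, z = 0,
    diameter = cfg$soma_diameter, length = cfg$soma_diameter,
    area = pi * cfg$soma_diameter^2, volume = pi * cfg$soma_diameter^3 / 6,
    n_units = 1, parent = NA_integer_)
  idx <- 1L
  # quasi-uniform branch directions with seeded jitter
  gold <- pi * (3 - sqrt(5))
  branch_segments <- integer(0)
  for (b in seq_len(cfg$n_primary)) {
    zdir <- 1 - 2 * (b - 0.5) / cfg$n_primary
    rxy <- sqrt(max(0, 1 - zdir^2))
    th <- gold * b + stats::runif(1, -0.2, 0.2)
    dir <- c(rxy * cos(th), rxy * sin(th), zdir)
    prev <- 1L
    for (s in seq_len(cfg$segments_per_branch)) {
      idx <- idx + 1L
      frac <- (s - 0.5) / cfg$segments_per_branch
      d <- cfg$taper[1] + (cfg$taper[2] - cfg$taper[1]) * frac
      pos <- dir * (soma_r + (s - 0.5) * seg_len)
      rows[[idx]] <- tibble::tibble(
        comp = idx, class = "branch", x = pos[1], y = pos[2], z = pos[3],
        diameter = d, length = seg_len,
        area = pi * d * seg_len, volume = pi * d^2 / 4 * seg_len,
        n_units = 1, parent = prev)
      dx <- if (prev == 1L) soma_r + seg_len / 2 else seg_len
      g_ax <- (pi * d^2 / 4) / (ra * dx) * 1e9           # nS
      g_df <- (pi * d^2 / 4) / dx                        # um (x D -> um^3/ms)
      edges[[length(edges) + 1L]] <-
        tibble::tibble(from = prev, to = idx, g_axial = g_ax, g_diff = g_df)
      branch_segments <- c(branch_segments, idx)
      prev <- idx
    }
  }
  if (cfg$leaflet_compartments > 0) {
    hosts <- sample(branch_segments, cfg$leaflet_compartments, replace = TRUE)
    ld <- stats::runif(cfg$leaflet_compartments,
                       cfg$leaflet_diameter[1], cfg$leaflet_diameter[2])
    ll <- stats::runif(cfg$leaflet_compartments,
                       cfg$leaflet_length[1], cfg$leaflet_length[2])
    u <- matrix(stats::rnorm(3 * cfg$leaflet_compartments), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    for (i in seq_len(cfg$leaflet_compartments)) {
      idx <- idx + 1L
      host <- rows[[hosts[i]]]
      off <- u[i, ] * (host$diameter / 2 + ll[i] / 2)
      jit <- stats::runif(1, -0.5, 0.5) * host$length
      # jitter along the host axis
      ax <- c(host$x, host$y, host$z)
      ax <- ax / max(sqrt(sum(ax^2)), 1e-9)
      pos <- c(host$x, host$y, host$z) + off + ax * jit
      nu <- cfg$leaflet_cluster
      rows[[idx]] <- tibble::tibble(
        comp = idx, class = "leaflet", x = pos[1], y = pos[2], z = pos[3],
        diameter = ld[i], length = ll[i],
        area = nu * pi * ld[i] * ll[i],
        volume = nu * pi * ld[i]^2 / 4 * ll[i],
        n_units = nu, parent = hosts[i])
      dx <- max(ll[i] / 2, 0.5)
      g_ax <- nu * (pi * ld[i]^2 / 4) / (ra * dx) * 1e9
      g_df <- nu * (pi * ld[i]^2 / 4) / dx
      edges[[length(edges) + 1L]] <-
        tibble::tibble(from = hosts[i], to = idx, g_axial = g_ax, g_diff = g_df)
    }
  }
  out <- dplyr::bind_rows(rows)
  out$dist_soma <- sqrt(out$x^2 + out$y^2 + out$z^2)
  ed <- dplyr::bind_rows(edges)
  sv <- sum(out$area) / sum(out$volume)
  structure(out, class = c("astro_morphology", class(out)),
            edges = ed, sv_ratio = sv)
}

#' @export
print.astro_morphology <- function(x, ...) {
  cat(sprintf("<astro_morphology> %d compartments (%d branch, %d leaflet clusters), surface/volume %.2f um^-1, arbor radius %.1f um\n",
              nrow(x), sum(x$class == "branch"), sum(x$class == "leaflet"),
              attr(x, "sv_ratio"), max(x$dist_soma)))
  NextMethod()
}

# graph Laplacians (voltage, nS; K+ diffusion, um) as dense matrices
morphology_laplacians <- function(graph) {
  n <- nrow(graph)
  ed <- attr(graph, "edges")
  G <- matrix(0, n, n)
  Gd <- matrix(0, n, n)
  for (i in seq_len(nrow(ed))) {
    a <- ed$from[i]; b <- ed$to[i]
    G[a, b] <- G[a, b] + ed$g_axial[i]
    G[b, a] <- G[b, a] + ed$g_axial[i]
    Gd[a, b] <- Gd[a, b] + ed$g_diff[i]
    Gd[b, a] <- Gd[b, a] + ed$g_diff[i]
  }
  diag(G) <- -rowSums(G)
  diag(Gd) <- -rowSums(Gd)
  list(G = G, Gd = Gd)
}
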