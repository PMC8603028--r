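#' Specification of a synthetic root crown
#'
#' Parameters of a maize-like excavated root crown: first-order
#' (crown/brace) roots inserted phyllotactically down a short stem stub,
#' emerging radially at sampled angles and bending downward, optionally
#' carrying laterals, rasterized as tapered tubes. The defaults describe a
#' mid-sized field crown at ~110 um voxels: a dozen first-order axes
#' 60-110 voxels (0.7-1.2 cm) long, base radius 3 voxels, emerging 40-72
#' degrees from vertical, with gentle curvature noise. Tubes are grown
#' collision-free against each other (only the stem is shared), so the
#' analytic ledger remains a valid oracle for the skeleton pipeline.
#'
#' @param n_first_order_roots Number of first-order roots.
#' @param insertion_angle_deg Range (degrees from vertical) of emergence
#'   angles; angles are spread deterministically over the range and
#'   interleaved down the stem so neighbouring roots diverge.
#' @param base_ring_radius_vx Radial offset of root bases from the stem
#'   axis (`NULL`: bases on the axis).
#' @param base_radius_vx Tube radius at the base, voxels.
#' @param taper_rate Radius lost per voxel of length (floored at 1 voxel).
#' @param root_length_vx Range of first-order root lengths, voxels.
#' @param laterals_per_cm Expected lateral branches per cm of first-order
#'   root (Poisson); 0 disables laterals.
#' @param lateral_length_vx Range of lateral lengths, voxels.
#' @param lateral_radius_vx Lateral tube radius, voxels.
#' @param curvature_sd_deg Per-step direction jitter, degrees.
#' @param trunk_length_vx Length of the vertical stem stub the roots
#'   insert on (0 disables it; roots then share one origin point).
#' @param voxel_size_um Voxel edge length, micrometres.
#' @param seed RNG seed; fixed seeds give bit-identical volumes.
#' @return A `crown_spec`.
#' @export
crown_spec <- function(n_first_order_roots = 12L,
                       insertion_angle_deg = c(40, 72),
                       base_ring_radius_vx = NULL,
                       base_radius_vx = 3,
                       taper_rate = 0.02,
                       root_length_vx = c(60, 110),
                       laterals_per_cm = 0,
                       lateral_length_vx = c(10, 25),
                       lateral_radius_vx = 1.4,
                       curvature_sd_deg = 1,
                       trunk_length_vx = 44,
                       voxel_size_um = 110,
                       seed = 1L) {
  stopifnot(n_first_order_roots >= 0,
            all(insertion_angle_deg >= 0 & insertion_angle_deg <= 90),
            base_radius_vx > 0, taper_rate >= 0, laterals_per_cm >= 0)
  structure(as.list(environment()), class = "crown_spec")
}

unit3 <- function(v) v / sqrt(sum(v^2))

# Grow a polyline from `origin` along `dir0` for `len` voxels in unit steps,
# jittering the direction each step and pulling it gently downward (+z).
# The pull is kept weak so roots steepen without converging onto parallel
# vertical tracks (which would fuse neighbouring tubes).
grow_polyline <- function(origin, dir0, len, jitter_sd, down_pull = 0.012) {
  n <- max(2L, ceiling(len))
  pts <- matrix(0, nrow = n + 1L, ncol = 3L)
  pts[1L, ] <- origin
  dir <- unit3(dir0)
  for (i in seq_len(n)) {
    dir <- unit3(dir + stats::rnorm(3L, 0, jitter_sd) + c(0, 0, down_pull))
    pts[i + 1L, ] <- pts[i, ] + dir
  }
  pts
}

polyline_length <- function(pts) {
  sum(sqrt(rowSums(diff(pts)^2)))
}

# Sample points along a polyline at ~`by` voxel spacing (always including
# vertices) with linearly interpolated radii. The tip end is trimmed by the
# tip radius so the stamped hemispherical cap ends at the polyline end and
# the ledger length equals the rasterized extent.
sample_polyline <- function(pts, r0, r1, by = 0.5, trim_end = 0) {
  seg <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  s_max <- max(total - trim_end, total / 2)
  s <- unique(c(seq(0, s_max, by = by), s_max))
  xyz <- apply(pts, 2L, function(col) stats::approx(cum, col, xout = s)$y)
  r <- r0 + (r1 - r0) * s / max(total, 1e-9)
  list(xyz = matrix(xyz, ncol = 3L), r = pmax(r, 1))
}

#' Generate a synthetic root crown with analytic ground truth
#'
#' First-order roots descend from the stem stub as tapered tubes with
#' curvature noise; laterals branch at Poisson-sampled positions. The grid
#' is sized to the generated geometry (with a margin of the largest tube
#' radius), so roots never leave the volume. The ground-truth ledger is
#' filled from the polylines before rasterization, making the generator an
#' oracle for the skeleton and trait pipeline.
#'
#' @param spec A [crown_spec()].
#' @return List with `volume` (a [binary_volume()]) and `truth`: total
#'   centreline length (voxels and cm), per-root lengths, tip count,
#'   first-order count, lateral count, voxel count, and the polylines.
#' @export
generate_crown <- function(spec) {
  stopifnot(inherits(spec, "crown_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  vox_per_cm <- um_per_cm / spec$voxel_size_um
  origin <- c(0, 0, 0)
  polylines <- list(); radii0 <- c(); radii1 <- c(); kinds <- c()

  trunk_r <- spec$base_radius_vx * 1.5
  trunk_len <- spec$trunk_length_vx
  if (trunk_len > 0) {
    polylines[[1L]] <- rbind(origin, origin + c(0, 0, trunk_len))
    radii0 <- trunk_r
    radii1 <- trunk_r
    kinds <- "trunk"
  }

  jitter <- sin(spec$curvature_sd_deg * pi / 180)
  ring_r <- if (is.null(spec$base_ring_radius_vx)) 0
            else spec$base_ring_radius_vx
  n1 <- spec$n_first_order_roots
  if (n1 > 0) {
    # phyllotactic insertion down the stem stub: consecutive bases step
    # ~150 degrees in azimuth and a few voxels in depth, so neighbouring
    # roots merge only with the (ledgered) trunk, never with each other
    azimuth <- (seq_len(n1) - 1L) * 150 * pi / 180 +
      stats::runif(n1, -0.15, 0.15)
    th_sorted <- seq(spec$insertion_angle_deg[1], spec$insertion_angle_deg[2],
                     length.out = max(n1, 2L))[seq_len(n1)]
    perm <- as.vector(rbind(seq_len(ceiling(n1 / 2)),
                            n1 + 1L - seq_len(ceiling(n1 / 2))))[seq_len(n1)]
    theta <- th_sorted[perm] * pi / 180
    lens <- stats::runif(n1, spec$root_length_vx[1], spec$root_length_vx[2])
    base_z <- if (trunk_len > 0)
      2 + (seq_len(n1) - 1L) / max(n1 - 1L, 1L) * (0.8 * trunk_len - 2) +
        stats::runif(n1, -0.5, 0.5)
    else rep(0, n1)
    grown <- list()   # first-order polylines with per-point radii
    for (i in seq_len(n1)) {
      base <- origin + c(ring_r * cos(azimuth[i]), ring_r * sin(azimuth[i]),
                         base_z[i])
      dir0 <- c(sin(theta[i]) * cos(azimuth[i]),
                sin(theta[i]) * sin(azimuth[i]), cos(theta[i]))
      r_tip <- max(1, spec$base_radius_vx - spec$taper_rate * lens[i])
      # tubes must not touch other first-order tubes (fused tubes would
      # make the ground-truth length ledger unverifiable); regrow with
      # fresh curvature noise until clear
      pl <- NULL
      for (try in 1:25) {
        cand <- grow_polyline(base, dir0, lens[i], jitter)
        if (!tubes_collide(cand, spec$base_radius_vx, r_tip, grown)) {
          pl <- cand; break
        }
      }
      if (is.null(pl)) pl <- cand
      grown[[length(grown) + 1L]] <-
        list(pts = pl, r = seq(spec$base_radius_vx, r_tip,
                               length.out = nrow(pl)))
      polylines[[length(polylines) + 1L]] <- pl
      radii0 <- c(radii0, spec$base_radius_vx)
      radii1 <- c(radii1, r_tip)
      kinds <- c(kinds, "first_order")
      if (spec$laterals_per_cm > 0) {
        len_cm <- polyline_length(pl) / vox_per_cm
        n_lat <- stats::rpois(1L, spec$laterals_per_cm * len_cm)
        if (n_lat > 0) {
          at <- sort(stats::runif(n_lat, 0.25, 0.9))
          for (a in at) {
            k <- max(2L, round(a * nrow(pl)))
            base <- pl[k, ]
            pdir <- unit3(pl[k, ] - pl[k - 1L, ])
            perp <- unit3(pracma_nullspace_dir(pdir))
            ang <- stats::runif(1, 50, 75) * pi / 180
            ldir <- unit3(cos(ang) * pdir + sin(ang) * perp)
            llen <- stats::runif(1, spec$lateral_length_vx[1],
                                 spec$lateral_length_vx[2])
            polylines[[length(polylines) + 1L]] <-
              grow_polyline(base, ldir, llen, jitter)
            radii0 <- c(radii0, spec$lateral_radius_vx)
            radii1 <- c(radii1, max(1, spec$lateral_radius_vx * 0.7))
            kinds <- c(kinds, "lateral")
          }
        }
      }
    }
  }
  if (!length(polylines)) stop("crown_spec generated no roots")

  all_pts <- do.call(rbind, polylines)
  rmax <- max(radii0, radii1)
  lo <- apply(all_pts, 2L, min) - rmax - 2
  hi <- apply(all_pts, 2L, max) + rmax + 2
  dims <- as.integer(ceiling(hi - lo) + 1L)
  meta <- volume_meta(dims[1], dims[2], dims[3], spec$voxel_size_um, 8L)

  mask <- array(FALSE, dim = dims)
  for (i in seq_along(polylines)) {
    sp <- sample_polyline(sweep(polylines[[i]], 2L, lo, "-"),
                          radii0[i], radii1[i],
                          trim_end = if (kinds[i] == "trunk") 0 else radii1[i])
    mask <- array(.stamp_spheres(sp$xyz, sp$r, dims, mask), dim = dims)
  }

  lens_vx <- vapply(polylines, polyline_length, 0)
  n_lat <- sum(kinds == "lateral")
  truth <- list(
    total_length_vx = sum(lens_vx),
    total_length_cm = sum(lens_vx) / vox_per_cm,
    root_lengths_vx = lens_vx,
    kinds = kinds,
    n_first_order = sum(kinds == "first_order"),
    n_laterals = n_lat,
    n_tips = sum(kinds == "first_order") + n_lat +
      (if (spec$trunk_length_vx > 0) 2L else 0L),
    n_voxels = sum(mask),
    polylines = lapply(polylines, function(p) sweep(p, 2L, lo, "-")))
  list(volume = binary_volume(mask, meta,
                              provenance = list(step = "generate_crown",
                                                seed = spec$seed)),
       truth = truth)
}

# TRUE when a candidate tube (polyline + tapered radius) would touch any
# previously grown tube. Points are subsampled for speed; the clearance is
# the sum of local radii plus half a voxel of rasterization slack.
tubes_collide <- function(pts, r0, r1, grown, slack = 0.75, skip_base = 10L) {
  if (!length(grown)) return(FALSE)
  n <- nrow(pts)
  sub <- seq(min(skip_base, n), n, by = 2L)  # bases merge into the trunk
  p <- pts[sub, , drop = FALSE]
  rp <- seq(r0, r1, length.out = n)[sub]
  for (g in grown) {
    gsub <- seq(min(skip_base, nrow(g$pts)), nrow(g$pts), by = 2L)
    q <- g$pts[gsub, , drop = FALSE]
    rq <- g$r[gsub]
    d2 <- outer(rowSums(p^2), rowSums(q^2), "+") - 2 * p %*% t(q)
    lim <- outer(rp, rq, "+") + slack
    if (any(d2 < lim^2)) return(TRUE)
  }
  FALSE
}

# A deterministic unit vector perpendicular to v.
pracma_nullspace_dir <- function(v) {
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit3(c(v[2] * a[3] - v[3] * a[2],
          v[3] * a[1] - v[1] * a[3],
          v[1] * a[2] - v[2] * a[1]))
}

#' Specification for phenotype simulation
#'
#' Additive genotype / environment / interaction / residual model with
#' independent Gaussian effects: `Y_ijk = mu + G_i + E_j + GE_ij + e_ijk`,
#' with variances `sigma2_G`, `sigma2_E`, `sigma2_GxE`, `sigma2_res`.
#' The defaults (2 environments, 3 replicates) mirror a two-irrigation
#' split-plot field design.
#'
#' @param n_genotypes Number of genotypes.
#' @param n_environments Number of environments `e`.
#' @param replicates Replicates per genotype-environment cell (scalar, or a
#'   `n_genotypes x n_environments` matrix for unbalanced designs).
#' @param sigma2_G,sigma2_E,sigma2_GxE,sigma2_res Variance components.
#' @param mu Grand mean.
#' @param n_traits Number of independent traits to simulate.
#' @param seed RNG seed.
#' @return A `pheno_sim_spec`.
#' @export
pheno_sim_spec <- function(n_genotypes = 50L, n_environments = 2L,
                           replicates = 3L, sigma2_G = 2, sigma2_E = 1,
                           sigma2_GxE = 1, sigma2_res = 1, mu = 10,
                           n_traits = 1L, seed = 1L) {
  stopifnot(n_genotypes >= 1, n_environments >= 1,
            all(c(sigma2_G, sigma2_E, sigma2_GxE, sigma2_res) >= 0))
  structure(as.list(environment()), class = "pheno_sim_spec")
}

#' Simulate a phenotype table with known variance structure
#'
#' @param spec A [pheno_sim_spec()].
#' @return Data frame with `sample_id`, `genotype`, `environment`,
#'   `replicate` and trait columns `trait_01`, ... Attribute `true_h2`
#'   holds the broad-sense heritability implied by the simulation variances,
#'   `sigma2_G / (sigma2_G + sigma2_GxE/e + sigma2_res/re)`.
#' @export
simulate_phenotypes <- function(spec) {
  stopifnot(inherits(spec, "pheno_sim_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  G <- spec$n_genotypes; E <- spec$n_environments
  reps <- spec$replicates
  if (is.matrix(reps)) stopifnot(nrow(reps) == G, ncol(reps) == E)
  else reps <- matrix(reps, G, E)
  cells <- expand.grid(g = seq_len(G), e = seq_len(E))
  rows <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    k <- reps[cells$g[i], cells$e[i]]
    if (k == 0) return(NULL)
    data.frame(genotype = cells$g[i], environment = cells$e[i],
               replicate = seq_len(k))
  }))
  n <- nrow(rows)
  traits <- matrix(0, n, spec$n_traits)
  for (t in seq_len(spec$n_traits)) {
    g_eff <- stats::rnorm(G, 0, sqrt(spec$sigma2_G))
    e_eff <- stats::rnorm(E, 0, sqrt(spec$sigma2_E))
    ge_eff <- matrix(stats::rnorm(G * E, 0, sqrt(spec$sigma2_GxE)), G, E)
    traits[, t] <- spec$mu + g_eff[rows$genotype] + e_eff[rows$environment] +
      ge_eff[cbind(rows$genotype, rows$environment)] +
      stats::rnorm(n, 0, sqrt(spec$sigma2_res))
  }
  colnames(traits) <- sprintf("trait_%02d", seq_len(spec$n_traits))
  out <- data.frame(sample_id = sprintf("S%05d", seq_len(n)),
                    genotype = factor(sprintf("G%03d", rows$genotype)),
                    environment = factor(sprintf("E%d", rows$environment)),
                    replicate = rows$replicate)
  out <- cbind(out, as.data.frame(traits))
  re <- mean(tapply(seq_len(n), out$genotype, length))
  attr(out, "true_h2") <- spec$sigma2_G /
    (spec$sigma2_G + spec$sigma2_GxE / E + spec$sigma2_res / re)
  out
}
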