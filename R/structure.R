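# Accessible-volume (AV) and accessible-contact-volume (ACV) dye modelling:
# the sterically allowed positions of a dye tethered by a flexible linker,
# computed on a regular grid with a geodesic (through-allowed-space) linker
# constraint. Mean inter-dye distances over two volumes predict the
# FRET-averaged R_DA used to screen candidate structures against measured
# distance sets.

#' Define a dye labelling site
#'
#' @param attachment Numeric xyz of the attachment atom, Angstrom.
#' @param linker_length Maximum linker extension, A (default 20).
#' @param linker_width Linker clash diameter, A (default 4.5).
#' @param dye_radius Dye clash radius, A (default 3.5); single-radius AV1
#'   model.
#' @return An object of class `label_site`.
#' @export
label_site <- function(attachment, linker_length = 20, linker_width = 4.5,
                       dye_radius = 3.5) {
  stopifnot(length(attachment) == 3, linker_length >= 0, linker_width >= 0,
            dye_radius >= 0)
  structure(list(attachment = as.numeric(attachment),
                 linker_length = linker_length, linker_width = linker_width,
                 dye_radius = dye_radius),
            class = "label_site")
}

# minimum distance from each grid point to any obstacle centre minus its
# radius (i.e. distance to the obstacle surface); obstacles is a data.frame
# x, y, z, radius
surface_distance <- function(pts, obstacles) {
  d <- rep(Inf, nrow(pts))
  for (k in seq_len(nrow(obstacles))) {
    dk <- sqrt((pts[, 1] - obstacles$x[k])^2 +
                 (pts[, 2] - obstacles$y[k])^2 +
                 (pts[, 3] - obstacles$z[k])^2) - obstacles$radius[k]
    d <- pmin(d, dk)
  }
  d
}

#' Compute a dye accessible (contact) volume
#'
#' Grid flood-fill from the attachment point: a grid position is allowed
#' when its distance to every obstacle surface exceeds the dye radius, and
#' its geodesic distance from the attachment — measured through allowed
#' space with 26-neighbour steps — does not exceed the linker length. In
#' ACV mode, positions within `contact_shell` of an obstacle surface are
#' up-weighted by `contact_weight`, modelling the dye's tendency to stick
#' to the macromolecular surface.
#'
#' @param obstacles data.frame `x`, `y`, `z`, `radius` (A), or NULL for
#'   free space.
#' @param site A [label_site()].
#' @param grid Grid spacing in A (default 1).
#' @param contact_shell Contact-shell thickness in A (default 3; ACV).
#' @param contact_weight Weight factor for contact positions (default 2;
#'   set 1 for plain AV).
#' @return An object of class `accessible_volume`: `points` (n x 3 matrix),
#'   `weights` (sum 1), `contact_fraction`, `grid`, `site`.
#' @export
compute_accessible_volume <- function(obstacles, site, grid = 1,
                                      contact_shell = 3, contact_weight = 2) {
  L <- site$linker_length
  att <- site$attachment
  if (L == 0)
    return(structure(list(points = matrix(att, 1, 3), weights = 1,
                          contact_fraction = 0, grid = grid, site = site),
                     class = "accessible_volume"))
  ax <- seq(-ceiling(L / grid), ceiling(L / grid)) * grid
  nx <- length(ax)
  pts <- as.matrix(expand.grid(x = att[1] + ax, y = att[2] + ax,
                               z = att[3] + ax))
  sdist <- if (is.null(obstacles) || nrow(obstacles) == 0)
    rep(Inf, nrow(pts)) else surface_distance(pts, obstacles)
  dye_ok <- sdist >= site$dye_radius
  path_ok <- sdist >= site$linker_width / 2
  allowed <- array(dye_ok & path_ok, dim = c(nx, nx, nx))
  ctr <- (nx + 1) / 2
  allowed[ctr, ctr, ctr] <- TRUE  # the attachment cell seeds the fill
  # geodesic distance by iterative 26-neighbour relaxation (NA = forbidden)
  dist <- array(Inf, dim = c(nx, nx, nx))
  dist[!allowed] <- NA
  dist[ctr, ctr, ctr] <- 0
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  steps <- sqrt(rowSums(offs^2)) * grid
  shift3 <- function(a, o) {
    n <- dim(a)[1]
    src <- lapply(1:3, function(k) {
      i <- seq_len(n) - o[k]
      i[i < 1 | i > n] <- NA
      i
    })
    a[src[[1]], src[[2]], src[[3]], drop = FALSE]
  }
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(offs))) {
      cand <- shift3(dist, offs[r, ]) + steps[r]
      upd <- which(!is.na(dist) & !is.na(cand) & cand < dist - 1e-12)
      if (length(upd)) { dist[upd] <- cand[upd]; changed <- TRUE }
    }
    if (!changed) break
  }
  keep <- as.vector(!is.na(dist) & is.finite(dist) & dist <= L)
  # The lattice geodesic overestimates Euclidean lengths by a few percent.
  # Points the chamfer pass rejected but that are within straight-line reach
  # and fully visible from the attachment are geodesically reachable with
  # the Euclidean length; admit them after a sampled line-of-sight check.
  euclid <- sqrt((pts[, 1] - att[1])^2 + (pts[, 2] - att[2])^2 +
                   (pts[, 3] - att[3])^2)
  contested <- which(!keep & as.vector(dye_ok & path_ok) & euclid <= L)
  if (length(contested)) {
    if (is.null(obstacles) || nrow(obstacles) == 0) {
      keep[contested] <- TRUE
    } else {
      nsamp <- max(2L, ceiling(L / (grid / 2)))
      fr <- seq(0, 1, length.out = nsamp)
      for (i in contested) {
        line <- cbind(att[1] + fr * (pts[i, 1] - att[1]),
                      att[2] + fr * (pts[i, 2] - att[2]),
                      att[3] + fr * (pts[i, 3] - att[3]))
        if (all(surface_distance(line, obstacles) >= site$linker_width / 2))
          keep[i] <- TRUE
      }
    }
  }
  if (sum(keep) <= 1)
    stop("labelling site is buried: no accessible volume")
  pts <- pts[keep, , drop = FALSE]
  w <- rep(1, nrow(pts))
  contact <- sdist[keep] <= site$dye_radius + contact_shell
  w[contact] <- contact_weight
  w <- w / sum(w)
  structure(list(points = pts, weights = w,
                 contact_fraction = sum(w[contact]),
                 grid = grid, site = site),
            class = "accessible_volume")
}

#' @export
print.accessible_volume <- function(x, ...) {
  cat(sprintf("<accessible_volume> %d grid points (%.3g A^3), contact %.2f\n",
              nrow(x$points), nrow(x$points) * x$grid^3, x$contact_fraction))
  invisible(x)
}

#' Mean inter-dye distance between two accessible volumes
#'
#' The FRET-relevant average is the weighted mean over all point pairs,
#' \eqn{\langle R_{DA}\rangle}, not the distance between mean positions.
#' Exact double-loop evaluation below `exact_limit` pairs, seeded weighted
#' pair sampling above it; the two volumes are ordered canonically so the
#' result is symmetric in its arguments.
#'
#' @param av1,av2 [compute_accessible_volume()] results.
#' @param n_samples Sampled pairs in the Monte-Carlo path.
#' @param seed Sampling seed.
#' @param exact_limit Maximum n1*n2 for exact enumeration.
#' @return A list: `mean` (A), `se` (0 for the exact path), `exact`.
#' @export
av_mean_distance <- function(av1, av2, n_samples = 2e5, seed = 1L,
                             exact_limit = 4e6) {
  n1 <- nrow(av1$points); n2 <- nrow(av2$points)
  if (n1 == 0 || n2 == 0) stop("empty accessible volume")
  key <- function(av) paste(nrow(av$points),
                            paste(sprintf("%.6f", colMeans(av$points)),
                                  collapse = ","))
  if (key(av1) > key(av2)) { tmp <- av1; av1 <- av2; av2 <- tmp }
  n1 <- nrow(av1$points); n2 <- nrow(av2$points)
  if (as.double(n1) * n2 <= exact_limit) {
    # exact weighted double loop, chunked over the first volume
    tot <- 0
    for (i in seq_len(n1)) {
      d <- sqrt((av2$points[, 1] - av1$points[i, 1])^2 +
                  (av2$points[, 2] - av1$points[i, 2])^2 +
                  (av2$points[, 3] - av1$points[i, 3])^2)
      tot <- tot + av1$weights[i] * sum(av2$weights * d)
    }
    return(list(mean = tot, se = 0, exact = TRUE))
  }
  set.seed(seed)
  i <- sample.int(n1, n_samples, replace = TRUE, prob = av1$weights)
  j <- sample.int(n2, n_samples, replace = TRUE, prob = av2$weights)
  d <- sqrt(rowSums((av1$points[i, , drop = FALSE] -
                       av2$points[j, , drop = FALSE])^2))
  list(mean = mean(d), se = stats::sd(d) / sqrt(n_samples), exact = FALSE)
}

#' Read obstacle atoms from a PDB file
#'
#' Heavy atoms with element-based van-der-Waals radii (H ignored).
#'
#' @param path PDB file path.
#' @return data.frame `x`, `y`, `z`, `radius`.
#' @export
read_obstacles_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  elem <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                substr(trimws(at$elety), 1, 1), at$elesy)))
  keep <- elem != "H"
  at <- at[keep, ]; elem <- elem[keep]
  vdw <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8, FE = 2.0, ZN = 1.39,
           MG = 1.73, NA. = 2.27, K = 2.75, CL = 1.75)
  r <- vdw[elem]
  r[is.na(r)] <- 1.7
  data.frame(x = at$x, y = at$y, z = at$z, radius = unname(r))
}

#' Screen candidate structures against a measured distance set
#'
#' For every candidate, predicted mean inter-dye distances per label pair
#' are compared with the measured set:
#' \eqn{\chi^2 = \sum_{pairs} ((\langle R_{model}\rangle - R_{meas})/
#' \Delta R)^2}, ranked per species; candidates with
#' \eqn{\chi^2/n \le 1} are flagged as within the acceptance band. Pairs a
#' candidate cannot provide are excluded from its chi-squared.
#'
#' @param model_distances data.frame `structure`, `pair_id`, `R_model`
#'   (use [av_mean_distance()] to build it), possibly NA.
#' @param measured data.frame `pair_id`, `species`, `R_meas`, `dR`.
#' @return data.frame `structure`, `species`, `chisq`, `n_pairs`,
#'   `chisq_red`, `rank` (within species), `accepted`.
#' @export
screen_structures <- function(model_distances, measured) {
  stopifnot(all(c("structure", "pair_id", "R_model") %in%
                  names(model_distances)),
            all(c("pair_id", "species", "R_meas", "dR") %in% names(measured)))
  out <- list()
  for (sp in unique(measured$species)) {
    ms <- measured[measured$species == sp, ]
    for (st in unique(model_distances$structure)) {
      md <- model_distances[model_distances$structure == st, ]
      rmod <- md$R_model[match(ms$pair_id, md$pair_id)]
      ok <- is.finite(rmod)
      chisq <- sum(((rmod[ok] - ms$R_meas[ok]) / ms$dR[ok])^2)
      out[[length(out) + 1]] <- data.frame(structure = st, species = sp,
                                           chisq = chisq, n_pairs = sum(ok))
    }
  }
  res <- do.call(rbind, out)
  res$chisq_red <- res$chisq / pmax(res$n_pairs, 1)
  res$rank <- stats::ave(res$chisq_red, res$species,
                         FUN = function(v) rank(v, ties.method = "first"))
  res$accepted <- res$chisq_red <= 1
  res[order(res$species, res$rank), ]
}
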