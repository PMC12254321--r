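#' Brownian droplet coalescence simulation
#'
#' Droplets random-walk in a periodic 2D box with per-step displacement
#' variance proportional to `diameter^-mobility_size_power` (Stokes-like
#' size-dependent mobility); droplets whose centre distance falls below the
#' sum of radii merge at their conserved-quantity-weighted centroid, with
#' multi-droplet contact chains merged transitively within a step. The
#' conserved quantity is total cross-sectional area (`sum r^2`, 2D movies)
#' or volume (`sum r^3`). For ordinary diffusion (`alpha = 1`) with
#' mobility power 1 and area conservation, Smoluchowski-type kinetics give
#' mean-diameter growth `d ~ t^(1/3)`, one third of the diffusive exponent.
#'
#' @param n_init Initial droplet count (>= 2).
#' @param init_radius Initial droplet radius, um (all equal).
#' @param n_steps Number of simulated steps.
#' @param config A [sim_config()]; `frame_interval` is the step duration.
#' @param box_size Periodic box edge, um. Default places the initial
#'   droplets at ~10% area fraction, typical of a condensate-rich nucleus
#'   and dense enough to reach the coalescence scaling regime quickly.
#' @param D_ref MSD amplitude (um^2/s^alpha) of a droplet of reference
#'   diameter `d_ref`.
#' @param d_ref Reference diameter for the mobility law, um.
#' @param alpha MSD exponent of droplet motion, in (0, 2); 1 = Brownian.
#' @param mobility_size_power Exponent p in `step variance ~ diameter^-p`.
#' @param conserve `"area"` or `"volume"`.
#' @param init_positions Optional n x 2 matrix of initial centres (um,
#'   inside the box); overrides random placement and is not checked for
#'   overlap, so droplets placed in contact merge on the first step.
#' @return A `coalescence_sim`: list with `droplets` (data frame: `frame`,
#'   `t_s`, `droplet_id`, `x_um`, `y_um` unwrapped, `radius_um`, `area_um2`,
#'   `diameter_um`), `box_size`, `conserve`, `alpha`, and
#'   `conserved_quantity` (per-frame totals).
#' @export
gen_coalescence <- function(n_init, init_radius = 0.5, n_steps = 400L,
                            config = sim_config(frame_interval = 1),
                            box_size = NULL, D_ref = 0.05, d_ref = 1,
                            alpha = 1, mobility_size_power = 1,
                            conserve = c("area", "volume"),
                            init_positions = NULL) {
  conserve <- match.arg(conserve)
  if (n_init < 2) stop("need at least two droplets", call. = FALSE)
  if (alpha <= 0 || alpha >= 2) stop("`alpha` must be in (0, 2)",
                                     call. = FALSE)
  if (is.null(box_size))
    box_size <- sqrt(n_init * pi * init_radius^2 / 0.10)
  dt <- config$frame_interval
  qpow <- if (conserve == "area") 2 else 3
  with_stream(child_seed(config$seed, "coalescence"), {
    # non-overlapping random initial placement (rejection sampling)
    x <- y <- numeric(0)
    if (!is.null(init_positions)) {
      x <- init_positions[, 1]; y <- init_positions[, 2]
      if (length(x) != n_init)
        stop("`init_positions` must have `n_init` rows", call. = FALSE)
    }
    tries <- 0L
    while (length(x) < n_init) {
      cx <- runif(1, 0, box_size); cy <- runif(1, 0, box_size)
      if (length(x)) {
        dx <- abs(x - cx); dx <- pmin(dx, box_size - dx)
        dy <- abs(y - cy); dy <- pmin(dy, box_size - dy)
        if (min(dx^2 + dy^2) < (2 * init_radius)^2) {
          tries <- tries + 1L
          if (tries > 1e4) stop("could not place non-overlapping droplets",
                                call. = FALSE)
          next
        }
      }
      x <- c(x, cx); y <- c(y, cy)
    }
    r <- rep(init_radius, n_init)
    id <- seq_len(n_init); next_id <- n_init + 1L
    # per-droplet fGn increment streams (unit variance per axis); merged
    # droplets start fresh streams, so correlation structure is exact
    # within a droplet's lifetime
    H <- alpha / 2
    make_stream <- function() {
      if (abs(H - 0.5) < 1e-12) NULL else
        list(gx = as.numeric(fgn_increments(n_steps, H, 1)),
             gy = as.numeric(fgn_increments(n_steps, H, 1)),
             ptr = 1L)
    }
    streams <- lapply(id, function(i) make_stream())
    xw <- x; yw <- y  # wrapped coords for contact tests; x,y stay unwrapped
    rows <- vector("list", n_steps + 1L)
    qtot <- numeric(n_steps + 1L)
    snap <- function(f) data.frame(frame = f, t_s = f * dt, droplet_id = id,
                                   x_um = x, y_um = y, radius_um = r,
                                   area_um2 = pi * r^2, diameter_um = 2 * r)
    rows[[1]] <- snap(0L); qtot[1] <- sum(r^qpow)
    for (step in seq_len(n_steps)) {
      # move: per-axis increment sd for lag dt is sqrt(D(d)/2) * dt^(alpha/2)
      sd_step <- sqrt(D_ref * (2 * r / d_ref)^(-mobility_size_power) / 2) *
        dt^(alpha / 2)
      if (is.null(streams[[1]]) || abs(H - 0.5) < 1e-12) {
        ddx <- rnorm(length(x), 0, sd_step)
        ddy <- rnorm(length(y), 0, sd_step)
      } else {
        ddx <- ddy <- numeric(length(x))
        for (q in seq_along(x)) {
          p <- streams[[q]]$ptr
          ddx[q] <- sd_step[q] * streams[[q]]$gx[p]
          ddy[q] <- sd_step[q] * streams[[q]]$gy[p]
          streams[[q]]$ptr <- p + 1L
        }
      }
      x <- x + ddx; y <- y + ddy
      xw <- (xw + ddx) %% box_size; yw <- (yw + ddy) %% box_size
      # transitive merging of contact chains
      if (length(x) > 1) {
        repeat {
          n <- length(x)
          dxm <- abs(outer(xw, xw, `-`)); dxm <- pmin(dxm, box_size - dxm)
          dym <- abs(outer(yw, yw, `-`)); dym <- pmin(dym, box_size - dym)
          touching <- (dxm^2 + dym^2 <= outer(r, r, `+`)^2) & upper.tri(dxm)
          if (!any(touching)) break
          # connected components of the contact graph
          comp <- seq_len(n)
          pairs <- which(touching, arr.ind = TRUE)
          for (e in seq_len(nrow(pairs))) {
            a <- comp[pairs[e, 1]]; b <- comp[pairs[e, 2]]
            if (a != b) comp[comp == b] <- a
          }
          nx <- x; ny <- y; nxw <- xw; nyw <- yw; nr <- r; nid <- id
          drop_idx <- integer(0)
          for (cc in unique(comp[duplicated(comp)])) {
            mem <- which(comp == cc)
            wts <- r[mem]^qpow
            # weighted centroid in the frame of the first member (minimal
            # image), then mapped back to both coordinate systems
            relx <- xw[mem] - xw[mem[1]]
            relx <- relx - box_size * round(relx / box_size)
            rely <- yw[mem] - yw[mem[1]]
            rely <- rely - box_size * round(rely / box_size)
            ox <- sum(wts * relx) / sum(wts)
            oy <- sum(wts * rely) / sum(wts)
            k <- mem[1]
            nx[k] <- x[k] + ox; ny[k] <- y[k] + oy
            nxw[k] <- (xw[k] + ox) %% box_size
            nyw[k] <- (yw[k] + oy) %% box_size
            nr[k] <- sum(r[mem]^qpow)^(1 / qpow)
            nid[k] <- next_id
            streams[[k]] <- make_stream()
            next_id <- next_id + 1L
            drop_idx <- c(drop_idx, mem[-1])
          }
          if (length(drop_idx)) {
            keep <- setdiff(seq_len(n), drop_idx)
            x <- nx[keep]; y <- ny[keep]; xw <- nxw[keep]; yw <- nyw[keep]
            r <- nr[keep]; id <- nid[keep]
            streams <- streams[keep]
          } else {
            x <- nx; y <- ny; xw <- nxw; yw <- nyw; r <- nr; id <- nid
          }
        }
      }
      rows[[step + 1L]] <- snap(step)
      qtot[step + 1L] <- sum(r^qpow)
    }
    structure(list(droplets = do.call(rbind, rows), box_size = box_size,
                   conserve = conserve, alpha = alpha,
                   frame_interval = dt, conserved_quantity = qtot),
              class = "coalescence_sim")
  })
}

#' @export
print.coalescence_sim <- function(x, ...) {
  n0 <- sum(x$droplets$frame == 0)
  nT <- sum(x$droplets$frame == max(x$droplets$frame))
  cat(sprintf("Coalescence simulation: %d -> %d droplets over %d steps (box %.3g um, conserve %s, alpha %.3g)\n",
              n0, nT, max(x$droplets$frame), x$box_size, x$conserve, x$alpha))
  invisible(x)
}

#' Droplet trajectories from a coalescence simulation
#'
#' Extracts per-droplet unwrapped positions as a `trajectory_set` (each
#' droplet id is a track; a merge ends both parent tracks and starts a new
#' one, so every track has stationary mobility).
#'
#' @param sim A `coalescence_sim`.
#' @return A `trajectory_set`.
#' @export
coalescence_tracks <- function(sim) {
  d <- sim$droplets
  as_trajectory_set(data.frame(track_id = d$droplet_id, frame = d$frame,
                               t_s = d$t_s, x_um = d$x_um, y_um = d$y_um),
                    sim$frame_interval)
}
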