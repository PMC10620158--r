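# Synthetic squamous epithelial sheet with a circular wound: jittered
# hexagonal tessellation, rank-dependent cortical edge intensity, PSF blur,
# additive noise, and full ground truth (cell ranks, wound geometry,
# suggested radial line ROIs).

#' Generate a synthetic wounded epithelial sheet image
#'
#' Cells of roughly `cell_diameter_um` tile the field as the Voronoi regions
#' of a jittered hexagonal lattice; a circular wound of `wound_area_mm2` sits
#' at the field centre with zero signal in its interior. Every boundary
#' between cells carries a cortical band whose intensity is set by the rank
#' (distance in cells) of the farther cell from the wound: the wound-margin
#' edge gets `edge_amplitudes[1]`, the margin/cell-1 edge `edge_amplitudes[2]`,
#' and so on; ranks past the list use its last (background) entry. The field
#' is blurred with a Gaussian PSF and Gaussian noise is added.
#'
#' @param edge_amplitudes Non-negative amplitudes (a.u.) for
#'   `[margin, cell1, cell2, cell3, background]`; shorter vectors are padded
#'   with their last value.
#' @param cell_diameter_um Cell diameter (default 50).
#' @param edge_thickness_um Cortical band thickness (default 25, so measured
#'   edge widths at half prominence fall inside the 20-40 um band).
#' @param wound_area_mm2 Wound area (default 0.05, inside the 0.02-0.125 mm2
#'   range of the assay).
#' @param psf_sigma_um Gaussian PSF sigma (default 3).
#' @param noise_sd Additive Gaussian noise sd (a.u.).
#' @param pixel_size_um Calibration (default 0.5 um/px).
#' @param field_size_um Field side length; `NULL` (default) sizes the field to
#'   hold the wound plus 5.5 cell ranks.
#' @param jitter_frac Lattice jitter as a fraction of the cell diameter.
#' @param n_rois Number of suggested radial line ROIs recorded in the truth.
#' @param seed Integer seed.
#' @return List with `image` (a [calibrated_image()]) and `truth`: cell table
#'   (`x_um`, `y_um`, `rank`), `edge_amplitudes`, `wound_center_um`,
#'   `wound_radius_um`, and `rois`, a tibble of radial line ROIs starting
#'   30 um inside the wound and running through margin-cell centres.
#' @export
make_sheet_image <- function(edge_amplitudes = c(200, 100, 80, 60, 40),
                             cell_diameter_um = 50, edge_thickness_um = 25,
                             wound_area_mm2 = 0.05, psf_sigma_um = 3,
                             noise_sd = 5, pixel_size_um = 0.5,
                             field_size_um = NULL, jitter_frac = 0.12,
                             n_rois = 8, seed = NULL) {
  check_nonneg(edge_amplitudes, "edge_amplitudes")
  check_positive_scalar(cell_diameter_um, "cell_diameter_um")
  check_positive_scalar(edge_thickness_um, "edge_thickness_um")
  check_positive_scalar(wound_area_mm2, "wound_area_mm2")
  check_nonneg(psf_sigma_um, "psf_sigma_um")
  check_nonneg(noise_sd, "noise_sd")
  check_positive_scalar(pixel_size_um, "pixel_size_um")
  amps <- c(edge_amplitudes, rep(edge_amplitudes[length(edge_amplitudes)],
                                 max(0, 5 - length(edge_amplitudes))))[1:5]
  d <- cell_diameter_um
  r_w <- sqrt(wound_area_mm2 / pi) * 1000
  if (is.null(field_size_um)) field_size_um <- 2 * (r_w + 5.5 * d)
  need <- 2 * (r_w + 1.5 * d)
  if (field_size_um < need) {
    rlang::abort(sprintf(
      "Wound of %.3g mm^2 (radius %.0f um) does not fit a %.0f um field (needs >= %.0f um).",
      wound_area_mm2, r_w, field_size_um, need))
  }
  npx <- round(field_size_um / pixel_size_um)
  ctr <- field_size_um / 2

  with_seed(seed, {
    # jittered hexagonal lattice of cell centres covering the field
    dy <- d * sqrt(3) / 2
    iy <- seq(-2L, ceiling(field_size_um / dy) + 2L)
    ix <- seq(-2L, ceiling(field_size_um / d) + 2L)
    grid <- expand.grid(ix = ix, iy = iy)
    jit <- matrix(runif(2 * nrow(grid), -jitter_frac * d, jitter_frac * d), ncol = 2)
    cx <- grid$ix * d + (grid$iy %% 2L) * d / 2 + jit[, 1]
    cy <- grid$iy * dy + jit[, 2]
    n_ix <- length(ix)
    key_of <- function(gix, giy) (giy + 2L) * n_ix + (gix + 2L) + 1L
    cmap <- integer(max(key_of(max(ix), max(iy))))
    cmap[key_of(grid$ix, grid$iy)] <- seq_len(nrow(grid))

    # nearest jittered centre per pixel, searching the 3x3 lattice block
    pxy <- ((seq_len(npx) - 1) + 0.5) * pixel_size_um
    X <- matrix(pxy, npx, npx, byrow = TRUE)   # col coordinate
    Y <- matrix(pxy, npx, npx)                 # row coordinate
    iy0 <- as.integer(round(Y / dy))
    ix0 <- as.integer(round((X - (iy0 %% 2L) * d / 2) / d))
    best_d2 <- matrix(Inf, npx, npx)
    lab <- matrix(0L, npx, npx)
    for (oy in -1:1) for (ox in -1:1) {
      id <- cmap[key_of(pmin(pmax(ix0 + ox, min(ix)), max(ix)),
                        pmin(pmax(iy0 + oy, min(iy)), max(iy)))]
      d2 <- (X - cx[id])^2 + (Y - cy[id])^2
      upd <- d2 < best_d2
      best_d2[upd] <- d2[upd]
      lab[upd] <- id[upd]
    }
    # the wound removes whole cells: all cells whose centres fall inside the
    # nominal disk (pixel-level masking would leave sliver margin cells, which
    # the tissue does not have)
    cd2 <- (cx - ctr)^2 + (cy - ctr)^2
    wound_ids <- which(cd2 <= r_w^2)
    if (length(wound_ids) == 0L) wound_ids <- which.min(cd2)
    lab[matrix(lab %in% wound_ids, npx, npx)] <- 0L

    # cell ranks by breadth-first search over the adjacency of the labelling
    hp <- cbind(as.vector(lab[, -npx]), as.vector(lab[, -1]))
    vp <- cbind(as.vector(lab[-npx, ]), as.vector(lab[-1, ]))
    pr <- rbind(hp, vp)
    pr <- pr[pr[, 1] != pr[, 2], , drop = FALSE]
    key <- pmin(pr[, 1], pr[, 2]) * (nrow(grid) + 1) + pmax(pr[, 1], pr[, 2])
    upair <- pr[!duplicated(key), , drop = FALSE]
    adj <- split(c(upair[, 2], upair[, 1]), c(upair[, 1], upair[, 2]))
    rank_of <- rep(NA_integer_, nrow(grid))
    frontier <- unique(adj[["0"]])
    lvl <- 1L
    while (length(frontier) > 0 && lvl <= 6L) {
      frontier <- frontier[frontier > 0]
      frontier <- frontier[is.na(rank_of[frontier])]
      rank_of[frontier] <- lvl
      frontier <- unique(unlist(adj[as.character(frontier)], use.names = FALSE))
      lvl <- lvl + 1L
    }
    rank_of[is.na(rank_of)] <- lvl

    # boundary pixels per amplitude class; wound counts as rank 0
    rk <- function(l) {
      r <- integer(length(l))
      nz <- l > 0L
      r[nz] <- rank_of[l[nz]]
      r
    }
    edge_cls <- matrix(0L, npx, npx)
    hsel <- which(lab[, -npx] != lab[, -1])
    hia <- arrayInd(hsel, c(npx, npx - 1L))
    va <- lab[-npx, ]; vb <- lab[-1, ]
    vsel <- which(va != vb)
    via <- arrayInd(vsel, c(npx - 1L, npx))
    upd_cls <- function(edge_cls, ra, rb, ia_idx, ib_idx) {
      cls <- pmin(pmax(ra, rb), 5L)
      edge_cls[ia_idx] <- pmax(edge_cls[ia_idx], cls)
      edge_cls[ib_idx] <- pmax(edge_cls[ib_idx], cls)
      edge_cls
    }
    if (nrow(hia) > 0) {
      ia_idx <- hia[, 1] + (hia[, 2] - 1L) * npx
      ib_idx <- hia[, 1] + hia[, 2] * npx
      edge_cls <- upd_cls(edge_cls, rk(lab[ia_idx]), rk(lab[ib_idx]), ia_idx, ib_idx)
    }
    if (nrow(via) > 0) {
      ia_idx <- via[, 1] + (via[, 2] - 1L) * npx
      ib_idx <- via[, 1] + 1L + (via[, 2] - 1L) * npx
      edge_cls <- upd_cls(edge_cls, rk(lab[ia_idx]), rk(lab[ib_idx]), ia_idx, ib_idx)
    }

    # cortical bands: pixels within half the band thickness of a class's
    # boundary pixels, intensity = that class's amplitude (max across classes)
    half_t_px <- edge_thickness_um / (2 * pixel_size_um)
    img <- matrix(0, npx, npx)
    for (k in 1:5) {
      if (amps[k] == 0 || !any(edge_cls == k)) next
      dist_k <- EBImage::distmap(1 - (edge_cls == k))
      img <- pmax(img, amps[k] * (dist_k <= half_t_px))
    }
    if (psf_sigma_um > 0) {
      img <- as.matrix(EBImage::gblur(img, sigma = psf_sigma_um / pixel_size_um))
    }
    if (noise_sd > 0) img <- img + rnorm(length(img), 0, noise_sd)
    img <- pmax(img, 0)

    cells <- tibble::tibble(id = seq_len(nrow(grid)), x_um = cx, y_um = cy,
                            rank = rank_of) |>
      dplyr::filter(.data$x_um >= 0, .data$x_um <= field_size_um,
                    .data$y_um >= 0, .data$y_um <= field_size_um)
    # suggested line ROIs: follow a chain of adjacent cell centres outward
    # from each margin cell (the in-silico analogue of drawing a line
    # perpendicular to the wound edge through the cell field), so boundary
    # crossings stay close to perpendicular
    margin_ids <- which(rank_of == 1L &
                          cx >= 0.1 * field_size_um & cx <= 0.9 * field_size_um &
                          cy >= 0.1 * field_size_um & cy <= 0.9 * field_size_um)
    # every tessellation boundary is the perpendicular bisector of a centre
    # pair, so a radial ray stays near-perpendicular to the edges it crosses
    # as long as the cell centres along it sit close to the ray; chains that
    # deviate are rejected, the analogue of an experimenter skipping regions
    # where a straight perpendicular line cannot be drawn cleanly
    chain_roi <- function(m) {
      u <- c(cx[m] - ctr, cy[m] - ctr)
      u <- u / sqrt(sum(u^2))
      w <- wound_ids[which.min((cx[wound_ids] - cx[m])^2 +
                                 (cy[wound_ids] - cy[m])^2)]
      chain <- c(m)
      cur <- m
      for (step in 1:3) {
        nb <- adj[[as.character(cur)]]
        nb <- setdiff(nb[nb > 0], chain)
        nb <- nb[rank_of[nb] == rank_of[cur] + 1L]
        if (length(nb) == 0L) return(NULL)
        v <- cbind(cx[nb] - cx[cur], cy[nb] - cy[cur])
        proj <- (v / sqrt(rowSums(v^2))) %*% u
        if (max(proj) < cos(50 * pi / 180)) return(NULL)
        cur <- nb[which.max(proj)]
        chain <- c(chain, cur)
      }
      # total-least-squares line through the four tissue-cell centres
      px_um <- cbind(cx[chain], cy[chain])
      com <- colMeans(px_um)
      dirv <- svd(sweep(px_um, 2, com))$v[, 1]
      if (sum(dirv * u) < 0) dirv <- -dirv
      # every tessellation edge is the perpendicular bisector of a centre
      # pair and is crossed near the pair's midpoint; keep the line only if
      # each crossing is close to perpendicular and near mid-edge — the
      # analogue of an experimenter skipping regions where a clean
      # perpendicular line cannot be drawn
      full <- rbind(c(cx[w], cy[w]), px_um)
      for (j in 1:4) {
        e <- full[j + 1, ] - full[j, ]
        ang_ok <- abs(sum(dirv * e) / sqrt(sum(e^2))) >= cos(35 * pi / 180)
        mid <- (full[j + 1, ] + full[j, ]) / 2
        rel <- mid - com
        dist_mid <- abs(rel[1] * dirv[2] - rel[2] * dirv[1])
        if (!ang_ok || dist_mid > 10) return(NULL)
      }
      t_mid1 <- sum(((full[1, ] + full[2, ]) / 2 - com) * dirv)
      tt <- sweep(px_um, 2, com) %*% dirv
      p_start <- com + (t_mid1 - 35) * dirv
      p_end <- com + (tt[4] + 45) * dirv
      lim <- c(2 * pixel_size_um, field_size_um - 2 * pixel_size_um)
      if (any(c(p_start, p_end) < lim[1]) || any(c(p_start, p_end) > lim[2])) {
        return(NULL)
      }
      c(p_start[2], p_start[1], p_end[2], p_end[1])  # (row, col) pairs
    }
    cand <- purrr::compact(purrr::map(margin_ids, chain_roi))
    if (length(cand) > n_rois) {
      cand <- cand[unique(round(seq(1, length(cand), length.out = n_rois)))]
    }
    rois <- purrr::imap_dfr(cand, function(p, i) {
      tibble::tibble(line = i,
                     start_row = p[1] / pixel_size_um,
                     start_col = p[2] / pixel_size_um,
                     end_row = p[3] / pixel_size_um,
                     end_col = p[4] / pixel_size_um,
                     wound_end = "start")
    })

    list(
      image = calibrated_image(img, pixel_size_um = pixel_size_um,
                               channel = "phalloidin"),
      truth = list(cells = cells, edge_amplitudes = amps,
                   wound_center_um = c(ctr, ctr), wound_radius_um = r_w,
                   true_ratios = amps[1:4] / amps[1], rois = rois, seed = seed)
    )
  })
}
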