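# Shared fixtures and independent oracles.

# A small config suitable for hand-built lattices.
tiny_config <- function(W = 8, H = 8) {
  cfg <- default_config(days = 0)
  cfg$geometry$width <- as.integer(W)
  cfg$geometry$height <- as.integer(H)
  cfg
}

# Build a random small state: n_cells blob-ish cells of random epithelial
# types on an otherwise empty lattice, plus random fields.
random_state <- function(W = 8, H = 8, n_cells = 3, with_links = FALSE,
                         lam_surf = 0.3) {
  sim <- empty_state(W, H, tiny_config(W, H))
  cfg <- sim$config
  cfg$potts$lambda_surface[] <- lam_surf
  cfg$potts$lambda_surface[c("MEDIUM", "LIMB", "MEMB", "STROMA", "WALL")] <- 0
  sim$config <- cfg
  # partition a random region into cells by nearest-seed assignment
  seeds <- cbind(x = sample(0:(W - 1), n_cells), y = sample(0:(H - 1), n_cells))
  types <- sample(c("STEM", "BASAL", "WING", "SUPER", "TEAR"), n_cells,
                  replace = TRUE)
  if (with_links) types[seq_len(min(2, n_cells))] <- "SUPER"
  idx <- expand.grid(x = 0:(W - 1), y = 0:(H - 1))
  keep <- runif(nrow(idx)) < 0.6
  idx <- idx[keep, ]
  d <- outer(seq_len(nrow(idx)), seq_len(n_cells), function(i, j)
    (idx$x[i] - seeds[j, 1])^2 + (idx$y[i] - seeds[j, 2])^2)
  owner <- max.col(-d)
  ids <- integer(n_cells)
  for (k in seq_len(n_cells)) {
    sel <- owner == k
    if (!any(sel)) next
    ids[k] <- register_cell2(sim, types[k], idx$x[sel], idx$y[sel],
                             tvol = sum(sel) + sample(-3:3, 1),
                             tsurf = 2 * sqrt(sum(sel)) + 4)
  }
  sim$fields$egf <- runif(W * H)
  sim$fields$bias <- runif(W * H)
  sim
}

register_cell2 <- function(sim, type, x, y, tvol, tsurf) {
  id <- add_cell(sim, type, x, y, tvol = tvol, tsurf = tsurf)
  id
}

# ---- independent full-Hamiltonian oracle -----------------------------------
# Recomputes the total energy by brute force over the whole lattice:
# contact over all 2nd-order neighbor pairs (each unordered pair once),
# quadratic volume and surface terms, Hookean link energies, and the
# chemotaxis "potential" is handled by the caller (it is not a state
# function, so the oracle compares contact+volume+surface+links only and the
# chemotaxis term is checked separately in closed form).
full_hamiltonian <- function(sim, links = NULL) {
  W <- sim$W; H <- sim$H
  cfg <- sim$config
  J <- contact_energy_table(cfg$potts$contact, cfg$potts$contact_default)
  cl <- sim$cells
  spin <- matrix(sim$spin, nrow = W)
  tym <- matrix(ifelse(sim$spin == 0L, 0L, cl$ctype[pmax(sim$spin, 1L)]),
                nrow = W)
  e_contact <- 0
  for (x in 1:W) for (y in 1:H) {
    for (d in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
      xn <- x + d[1]; yn <- y + d[2]
      if (xn < 1 || xn > W || yn < 1 || yn > H) next
      if (spin[x, y] != spin[xn, yn])
        e_contact <- e_contact + J[tym[x, y] + 1, tym[xn, yn] + 1]
    }
  }
  e_vol <- 0; e_surf <- 0
  lamv <- cfg$potts$lambda_volume; lams <- cfg$potts$lambda_surface
  for (id in which(cl$alive[seq_len(cl$n)])) {
    tp <- type_name(cl$ctype[id])
    vox <- which(sim$spin == id)
    V <- length(vox)
    if (lamv[[tp]] > 0) e_vol <- e_vol + lamv[[tp]] * (V - cl$tvol[id])^2
    if (lams[[tp]] > 0) {
      S <- 0
      for (i in vox) {
        x <- (i - 1) %% W + 1; y <- (i - 1) %/% W + 1
        for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          xn <- x + d[1]; yn <- y + d[2]
          if (xn < 1 || xn > W || yn < 1 || yn > H) S <- S + 1
          else if (spin[xn, yn] != id) S <- S + 1
        }
      }
      e_surf <- e_surf + lams[[tp]] * (S - cl$tsurf[id])^2
    }
  }
  e_link <- 0
  if (!is.null(links) && nrow(links) > 0) {
    for (r in seq_len(nrow(links))) {
      i1 <- links[r, 1]; i2 <- links[r, 2]
      v1 <- which(sim$spin == i1); v2 <- which(sim$spin == i2)
      c1 <- c(mean((v1 - 1) %% W), mean((v1 - 1) %/% W))
      c2 <- c(mean((v2 - 1) %% W), mean((v2 - 1) %/% W))
      L <- sqrt(sum((c1 - c2)^2))
      e_link <- e_link + links[r, 3] * (L - links[r, 4])^2
    }
  }
  unname(e_contact + e_vol + e_surf + e_link)
}

# Apply a copy of the spin at voxel a onto voxel b directly to a deep copy of
# the state (for before/after oracle comparisons).
copy_voxel <- function(sim, a, b) {
  snap <- snapshot_state(sim)
  sim2 <- restore_state(snap)
  sim2$spin[b + 1L] <- sim2$spin[a + 1L]
  refresh_stats(sim2)
  sim2
}

# A stratified mini-tissue for composition tests: stroma, membrane, one
# basal row, one wing row, supers, tear.
mini_tissue <- function(W = 20, H = 20) {
  cfg <- tiny_config(W, H)
  cfg$geometry$stroma_depth <- 4L
  cfg$geometry$limbal_voxels <- 6L
  sim <- empty_state(W, H, cfg)
  sim$wall_id <- add_cell(sim, "WALL", c(rep(0L, H), rep(W - 1L, H)),
                          c(0:(H - 1), 0:(H - 1)))
  sim$stroma_id <- add_cell(sim, "STROMA", rep(1:(W - 2), each = 4),
                            rep(0:3, W - 2))
  sim$limb_id <- add_cell(sim, "LIMB", 1:5, rep(4L, 5))
  sim$memb_id <- add_cell(sim, "MEMB", 6:(W - 2), rep(4L, W - 7))
  sim
}
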