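# Fixture builders shared across test files. Everything is generated in code.

# a regular polygon basal lamina centred at `centre`
lamina_circle <- function(radius = 50, centre = c(0, 0), n = 32L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(centre[1L] + radius * cos(t), centre[2L] + radius * sin(t))
}

# hand-build a section with one cell at a chosen azimuth and planted angle;
# phase picks the landmark construction
section_one_cell <- function(theta_deg, azimuth_deg = 30, phase = "anaphase",
                             follicle_id = "f", sep = 4) {
  az <- azimuth_deg * pi / 180
  centre <- 35 * c(cos(az), sin(az))
  sp <- az + theta_deg * pi / 180
  sp_dir <- c(cos(sp), sin(sp))
  cell <- if (phase == "anaphase") {
    mitotic_cell("c1", centre, "anaphase",
                 landmarks_a = rbind(centre - sep * sp_dir),
                 landmarks_b = rbind(centre + sep * sp_dir))
  } else {
    plate <- c(-sp_dir[2L], sp_dir[1L])
    mitotic_cell("c1", centre, "metaphase",
                 landmarks = rbind(centre + sep * plate, centre - sep * plate))
  }
  follicle_section(follicle_id, c(0, 0), lamina_circle(), list(cell),
                   oocyte_radius = 20)
}

# apply a rigid motion (rotation by phi degrees then translation) to a section
transform_section <- function(section, phi_deg = 0, shift = c(0, 0)) {
  phi <- phi_deg * pi / 180
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2L, 2L)
  tp <- function(p) as.vector(R %*% as.numeric(p)) + shift
  tm <- function(m) t(apply(m, 1L, tp))
  cells <- lapply(section$cells, function(cell) {
    mitotic_cell(cell$cell_id, tp(cell$centre), cell$phase,
                 landmarks = if (!is.null(cell$landmarks)) tm(cell$landmarks),
                 landmarks_a = if (!is.null(cell$landmarks_a)) tm(cell$landmarks_a),
                 landmarks_b = if (!is.null(cell$landmarks_b)) tm(cell$landmarks_b))
  })
  follicle_section(section$follicle_id, tp(section$oocyte_centre),
                   tm(section$basal_lamina), cells,
                   oocyte_radius = section$oocyte_radius,
                   layer_count = section$layer_count)
}

# brute-force sup-distance between the ECDF of u and the uniform CDF,
# evaluated on a fine grid plus the jump points (both one-sided limits)
brute_force_uniform_D <- function(u, grid_n = 1e6) {
  n <- length(u)
  grid <- c(seq(0, 1, length.out = grid_n), sort(u))
  Fhat <- ecdf(u)
  d_at <- abs(Fhat(grid) - grid)                  # right limit at each point
  d_left <- abs((rank(sort(u)) - 1) / n - sort(u))  # left limit at jumps
  max(max(d_at), max(d_left))
}

# exact two-sided Mann-Whitney p by full enumeration of rank assignments
enumerate_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(N, n1)
  us <- apply(combs, 2L, function(ix) sum(ix) - n1 * (n1 + 1) / 2)
  p_le <- mean(us <= u_obs + 1e-9)
  p_ge <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
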