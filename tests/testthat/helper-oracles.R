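# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately avoid the package's code paths (and igraph): the
# readiness oracle spells out the published conjunctions literally, the
# shortest-path oracles are a plain O(n^2) Dijkstra and Floyd-Warshall.

# one fully-stocked assessed facility; override any field via ...
make_facility <- function(id = "F-01", district = "DAKAR_CENTRE", ...) {
  rec <- list(
    facility_id = id, district = district, facility_type = "HEALTH_POST",
    x = 0, y = 0, assessed = TRUE, refers_to = NA_character_,
    running_water = TRUE, decontamination_buckets = TRUE,
    safety_boxes = TRUE, soap = TRUE, removal_days_per_week = 5L,
    n_trained_removal = 1L, n_trained_ultrasound = 1L,
    syringes = TRUE, local_anesthetic = TRUE, sterile_band_aids = TRUE,
    scalpel_with_blade = TRUE, curved_forceps = TRUE,
    straight_forceps = TRUE, antiseptic = TRUE, cotton_balls = TRUE,
    sterile_gauze = TRUE, vasectomy_forceps = TRUE,
    ultrasound_machine = TRUE, sterile_towels = TRUE,
    examination_table = TRUE, sterile_surgical_drape = TRUE,
    sterile_equipment_tray = TRUE, autoclave = TRUE)
  over <- list(...)
  rec[names(over)] <- over
  as.data.frame(rec, stringsAsFactors = FALSE)
}

make_survey <- function(...) {
  facility_survey(do.call(rbind, list(...)))
}

# random assessed facility: each checklist field drawn independently
random_facility <- function(id) {
  flags <- c("running_water", "decontamination_buckets", "safety_boxes",
             "soap", "syringes", "local_anesthetic", "sterile_band_aids",
             "scalpel_with_blade", "curved_forceps", "straight_forceps",
             "antiseptic", "cotton_balls", "sterile_gauze",
             "vasectomy_forceps", "ultrasound_machine", "sterile_towels",
             "examination_table", "sterile_surgical_drape",
             "sterile_equipment_tray")
  args <- as.list(setNames(as.logical(rbinom(length(flags), 1, 0.8)), flags))
  args$removal_days_per_week <- sample(0:7, 1)
  args$n_trained_removal <- sample(0:3, 1)
  args$n_trained_ultrasound <- sample(0:2, 1)
  do.call(make_facility, c(list(id = id), args))
}

# literal transcription of the published readiness conditions
oracle_level <- function(f) {
  gen <- f$running_water && f$decontamination_buckets && f$safety_boxes &&
    f$soap && f$removal_days_per_week >= 5
  hr_reg <- f$n_trained_removal >= 1
  hr_dif <- hr_reg && f$n_trained_ultrasound >= 1
  eq_reg <- f$syringes && f$local_anesthetic && f$sterile_band_aids &&
    f$scalpel_with_blade && f$curved_forceps && f$straight_forceps &&
    (f$sterile_gauze || (f$antiseptic && f$cotton_balls))
  eq_dif <- eq_reg && f$vasectomy_forceps && f$ultrasound_machine &&
    f$sterile_towels && f$examination_table && f$sterile_surgical_drape &&
    f$sterile_equipment_tray
  if (gen && hr_dif && eq_dif) "DIFFICULT"
  else if (gen && hr_reg && eq_reg) "REGULAR"
  else "NOT_READY"
}

# multi-source Dijkstra over an 8-connected speed raster, written directly
# against the matrix (linear scan extraction, no heap, no igraph)
oracle_accumulate <- function(speed, cell_size, sources_rc) {
  nr <- nrow(speed); nc <- ncol(speed)
  tpm <- 60 / (1000 * speed)
  dist <- rep(Inf, nr * nc)
  done <- rep(FALSE, nr * nc)
  passable <- !is.na(as.vector(speed))
  done[!passable] <- TRUE
  for (s in sources_rc) dist[(s[2] - 1) * nr + s[1]] <- 0
  repeat {
    cand <- which(!done & is.finite(dist))
    if (length(cand) == 0) break
    u <- cand[which.min(dist[cand])]
    done[u] <- TRUE
    ur <- ((u - 1) %% nr) + 1; uc <- ((u - 1) %/% nr) + 1
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      vr <- ur + dr; vc <- uc + dc
      if (vr < 1 || vr > nr || vc < 1 || vc > nc) next
      v <- (vc - 1) * nr + vr
      if (done[v] || !passable[v]) next
      step <- cell_size * sqrt(dr^2 + dc^2) * (tpm[ur, uc] + tpm[vr, vc]) / 2
      if (dist[u] + step < dist[v]) dist[v] <- dist[u] + step
    }
  }
  out <- matrix(dist, nr, nc)
  out[is.infinite(out)] <- NA
  out[!passable] <- NA
  out
}

# all-pairs shortest paths by Floyd-Warshall on a road_network edge list
oracle_floyd_warshall <- function(nodes, edges) {
  n <- nrow(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes$id, nodes$id))
  diag(d) <- 0
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    d[a, b] <- min(d[a, b], edges$length_m[i])
    d[b, a] <- d[a, b]
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# random connected speed raster with optional no-data holes
random_speed_raster <- function(nr, nc, cell_size = 100, p_na = 0.1) {
  v <- matrix(runif(nr * nc, 0.5, 60), nr, nc)
  v[runif(nr * nc) < p_na] <- NA
  r <- grid_raster(v, cell_size)
  class(r) <- c("cost_surface", class(r))
  r
}

# a uniform-speed cost surface
uniform_surface <- function(nr, nc, speed, cell_size = 100) {
  r <- grid_raster(matrix(speed, nr, nc), cell_size)
  class(r) <- c("cost_surface", class(r))
  r
}

cell_center_point <- function(r, row, col) {
  cs <- r$cell_size_m
  data.frame(x = r$xmin + (col - 0.5) * cs,
             y = r$ymin + (nrow(r$values) - row + 0.5) * cs)
}
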