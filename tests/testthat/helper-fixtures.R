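# Small fixtures built in code at test time.

tiny_grid <- function(n = 6, sp = 2) voxel_grid(rep(n, 3), rep(sp, 3))

# hand-built sparse spot contribution (bypasses the engine) for metric tests
fake_spot_dose <- function(grid, idx, dose, let = rep(2, length(idx)),
                           field_id = "F1", spot_id = 1L) {
  structure(list(field_id = field_id, spot_id = spot_id,
                 idx = as.integer(idx), dose = as.numeric(dose),
                 let = as.numeric(let)),
            grid_sig = pbsmdr:::grid_signature(grid),
            class = "spot_dose")
}

# a random set of sparse spots on a tiny grid, plus a matching log
random_sparse_case <- function(grid, n_spots = 8, n_fields = 2, seed = 1) {
  set.seed(seed)
  nv <- prod(grid$dims)
  sds <- lapply(seq_len(n_spots), function(i) {
    k <- sample(3:12, 1)
    fake_spot_dose(grid, idx = sample.int(nv, k),
                   dose = runif(k, 1e-4, 0.05),
                   let = runif(k, 0.5, 10),
                   field_id = sprintf("F%d", (i %% n_fields) + 1L),
                   spot_id = i)
  })
  log <- data.frame(
    field_id = vapply(sds, function(s) s$field_id, character(1)),
    spot_id = vapply(sds, function(s) s$spot_id, integer(1)))
  log$duration_us <- sample(2000:9000, n_spots)
  log$t_start_us <- cumsum(c(0, head(log$duration_us, -1) + 2000))
  log$t_end_us <- log$t_start_us + log$duration_us
  list(spot_doses = sds, log = log)
}

full_mask <- function(grid, name = "ALL") {
  structure_mask(name, grid, array(TRUE, dim = grid$dims))
}

# reduced-size cohort config for fast end-to-end tests
small_run_config <- function() {
  spec <- default_cohort_spec()
  spec$cases <- spec$cases[c(1, 3), ]
  spec$spot_spacing_mm <- 6
  spec$layer_spacing_mm <- 8
  cohort_run_config(dims = c(40, 40, 40), spacing = c(3, 3, 3),
                    cohort_spec = spec)
}

# the full default cohort run is expensive; compute once per session
.run_cache <- new.env(parent = emptyenv())
default_cohort_run <- function(seed = 1) {
  key <- paste0("run", seed)
  if (is.null(.run_cache[[key]]))
    .run_cache[[key]] <- run_cohort(cohort_run_config(), seed = seed)
  .run_cache[[key]]
}
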