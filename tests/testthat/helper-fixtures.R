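# shared fixture builders; everything is generated in code at test time

tiny_grid <- function(n = 12) grid_geometry(c(n, n, n))

# small planted-effect cohort used across modules
tiny_cohort <- function(n_per_group = 6, shape = 12, effect_size = 0.1,
                        noise_sigma = 0.1, seed = 2, ...) {
  generate_cohort(synth_config(grid = tiny_grid(shape),
                               n_per_group = n_per_group,
                               effect_size = effect_size,
                               noise_sigma = noise_sigma, seed = seed, ...))
}

# deterministic two-region atlas split along y; the default planted effect
# lies in the anterior (high-y) half, i.e. entirely inside region 1
two_region_atlas <- function(mask, grid) {
  labels <- array(0L, dim(mask))
  mid <- dim(mask)[2] / 2
  for (j in seq_len(dim(mask)[2])) {
    labels[, j, ][mask[, j, ]] <- if (j > mid) 1L else 2L
  }
  structure(list(labels = labels,
                 names = stats::setNames(c("anterior", "posterior"), 1:2),
                 sides = stats::setNames(c("R", "L"), 1:2),
                 grid = grid),
            class = "label_atlas")
}

# printed baseline-characteristics counts used as regression inputs
table1_counts <- function() {
  list(
    age_cee_alone = cbind(c(123, 93, 38), c(128, 89, 39)),
    age_cee_mpa = cbind(c(220, 147, 53), c(225, 150, 60)),
    age_ht = cbind(c(343, 240, 91), c(353, 239, 99)),
    smoking_cee_alone = cbind(c(147, 95, 9), c(142, 98, 15)),
    smoking_cee_mpa = cbind(c(248, 152, 18), c(247, 168, 15)),
    prior_cvd_cee_alone = cbind(c(233, 3, 18), c(233, 4, 19)),
    prior_ht_cee_alone = cbind(c(129, 125), c(124, 132))
  )
}

table1_printed <- c(age_cee_alone = 90.82, age_cee_mpa = 87.94,
                    age_ht = 87.33, smoking_cee_alone = 44.90,
                    smoking_cee_mpa = 63.60, prior_cvd_cee_alone = 92.22,
                    prior_ht_cee_alone = 59.56)
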