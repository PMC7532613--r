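# Shared fixtures: random DVHs and the brute-force per-voxel oracle.

# random differential DVH on a uniform grid, normalised exactly
random_diff_dvh <- function(n_bins = 100, max_dose = 60, organ = "lung") {
  edges <- seq(0, max_dose, length.out = n_bins + 1)
  v <- stats::rexp(n_bins)
  dvh(edges, v / sum(v), form = "differential", organ = organ)
}

# random per-voxel dose list mixing an in-field and a low-dose component
random_voxel_doses <- function(n, d_max = 50) {
  infield <- stats::rbeta(round(n * 0.4), 3, 1.5) * d_max
  bath <- pmin(stats::rexp(n - length(infield), rate = 1 / 2), d_max)
  c(infield, bath)
}

# closed-form OED of a uniform dose under each model
closed_form_oed <- function(D, model, alpha = 0.044, delta = 0.139) {
  switch(model,
    linear = D,
    linear_exponential = D * exp(-alpha * D),
    linear_plateau = (1 - exp(-delta * D)) / delta
  )
}

# brute-force per-voxel OED: mean of the response over the voxel list
voxel_oed <- function(doses, model, alpha = 0.044, delta = 0.139) {
  mean(vapply(doses, closed_form_oed, 0, model = model,
              alpha = alpha, delta = delta))
}

# five-patient cohort of identical uniform-dose plans
uniform_cohort <- function(doses_by_organ, n = 5, label = "test",
                           group = 2, technique = "PT", setup = "FB") {
  patients <- lapply(seq_len(n), function(i) {
    dvhs <- lapply(names(doses_by_organ), function(o) {
      uniform_dvh(doses_by_organ[[o]], organ = o)
    })
    names(dvhs) <- names(doses_by_organ)
    patient_plan(sprintf("%s_P%02d", label, i), dvhs)
  })
  cohort(label, patients, group = group, technique = technique, setup = setup)
}
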