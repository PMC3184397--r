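# Shared fixtures, computed once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

fix_model <- function() cached("model", default_redox_model())

fix_control <- function() {
  refs <- reference_patients()
  refs[refs$label == "Control", ]
}

fix_patient <- function(lab) {
  refs <- reference_patients()
  refs[refs$label == lab, ]
}

fix_control_ss <- function() {
  cached("control_ss", find_steady_state(fix_model(), fix_control()))
}

fix_control_traj <- function() {
  cached("control_traj",
         run_perturbation(fix_model(), fix_control(), fix_control_ss()))
}

fix_reference_cohort <- function() {
  cached("reference_cohort", evaluate_cohort(reference_patients(), fix_model()))
}

# independent two-pass Pearson correlation (test oracle)
pearson_two_pass <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

dynamic_species <- c("h2o2", "o2minus", "gsh", "gssg",
                     "nadph", "nadp", "g6p", "gl6p")

# random non-negative full state over the default network's species
random_state <- function(scale = 100) {
  s <- stats::runif(12, 0, scale)
  names(s) <- c(dynamic_species, "h2o2_ext", "atp", "bpg23", "glc")
  s
}

write_toy_model <- function(path = tempfile(fileext = ".yaml"),
                            k = 0.2, a = 3, x0 = 0.5) {
  yaml::write_yaml(list(
    name = "toy",
    species = list(list(name = "x", initial = x0, clamped = FALSE),
                   list(name = "a", initial = a, clamped = TRUE)),
    reactions = list(list(name = "relax", law = "diffusion",
                          stoich = list(x = 1),
                          params = list(k = k, source = "a", target = "x")))),
    path)
  path
}
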