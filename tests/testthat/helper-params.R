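# Shared fixtures: the bundled profile is loaded once per test run; small
# mutations are made on deep copies.

.params_cache <- new.env(parent = emptyenv())

test_params <- function() {
  if (is.null(.params_cache$p)) .params_cache$p <- load_params()
  .params_cache$p
}

# re-serialize a mutated raw profile and load it through the validator
load_mutated <- function(mutate) {
  raw <- yaml::read_yaml(default_config_path())
  raw <- mutate(raw)
  load_params(text = yaml::as.yaml(raw, precision = 15))
}

# identity matrices with the nomcea_matrices contract, for closed-form checks
identity_matrices <- function(init = c(1, 0, 0, 0, 0, 0)) {
  m <- diag(6)
  dimnames(m) <- list(c("A","B","C","D","E","F"), c("A","B","C","D","E","F"))
  structure(rep(list(m), 5), class = "nomcea_matrices", strategy = "nom",
            initial_occupancy = setNames(init, c("A","B","C","D","E","F")))
}

flat_utilities <- function(u = 1) {
  list(initial_state = u, long_term_stable = u, salvage_surgery = u,
       local_recurrence = u, distant_recurrence = u, local_and_distant = u,
       death = 0)
}

zero_costs <- function() matrix(0, 6, 5, dimnames = list(c("A","B","C","D","E","F"), 1:5))
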