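# fixtures are built in code; nothing is read from disk

tiny_schema <- function() {
  feature_schema(list(
    feature_spec("age", "numeric", group = "clinical",
                 in_domain_knowledge = TRUE),
    feature_spec("lvef", "numeric", group = "echo"),
    feature_spec("af", "binary", group = "ecg", in_domain_knowledge = TRUE),
    feature_spec("valve_type", "categorical",
                 categories = c("balloon", "self", "mechanical"),
                 group = "procedural")),
    outcome_name = "lbbb")
}

tiny_cohort <- function() {
  vals <- cbind(age = c(70, 80, 90, 75, 85, 65),
                lvef = c(55, 60, 40, 45, 50, 35),
                af = c(0, 1, 0, 1, 0, 1),
                valve_type = c(0, 1, 2, 0, 1, 2))
  cohort_table(vals, c(0, 1, 0, 1, 0, 1), tiny_schema())
}

# small planted cohort for selector tests
small_gen <- function(seed = 1, n = 60, effect = 2, p_num = 4) {
  generate_cohort(generator_config(
    n = n, event_rate = 0.4, n_numeric = p_num, n_binary = 1,
    n_categorical = 1,
    informative = data.frame(index = 1, effect = effect),
    seed = seed))
}

small_hp <- function(...) {
  args <- utils::modifyList(
    list(d_token = 8L, n_heads = 2L, epochs = 5L, lr = 1e-3,
         lambda1 = 1e-3, lambda2 = 1e-4, ridge = 1e-2, seed = 42L),
    list(...))
  do.call(selector_hyperparams, args)
}

preprocessed <- function(tab) apply_preprocessor(fit_preprocessor(tab), tab)

# edit selector parameters in place and refresh the flat vector
with_params <- function(selector, fn) {
  selector$params <- fn(selector$params)
  selector$flat <- t2select:::flatten_params(selector$params)
  selector
}
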