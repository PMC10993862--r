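# Shared fixtures, memoised so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  hit <- .fixtures[[name]]
  if (!is.null(hit)) return(hit)
  val <- builder()
  .fixtures[[name]] <- val
  val
}

pieg_fixture <- function() fixture("pieg_spec", function() pieg_spec(3L, 3L, 5L))

cfa_fixture <- function() fixture("cfa_spec", function()
  as_numeric_spec(pieg_spec(3L, 3L, 5L)))

# one scenario-1 ordinal sample and its score-guided tree, reused widely
scenario1_fixture <- function() fixture("scenario1_ordinal", function()
  make_scenario1("ordinal", seed = 1L))

scenario1_tree_fixture <- function() fixture("scenario1_tree", function()
  suppressWarnings(mgr_tree(scenario1_fixture()$data, scenario1_fixture()$Z,
                            scenario1_fixture()$manifest$spec,
                            mgr_tree_control(seed = 1L))))

# converged ML fit on CFA-twin data with known parameters
cfa_fit_fixture <- function() fixture("cfa_fit", function() {
  spec <- cfa_fixture()
  par <- sample_pieg_parameters(spec, seed = 42L)
  dat <- simulate_cfa(par, 2000L, seed = 7L)
  list(spec = spec, params = par, data = dat, fit = fit_ml(spec, dat))
})

# tiny two-item single-factor spec for closed-form checks
two_item_spec <- function(residuals = "free") {
  L <- matrix(c(1, 1), 2, 1, dimnames = list(c("y1", "y2"), "xi"))
  mgr_spec(L, response = "numeric", residuals = residuals)
}

expect_partition <- function(tree, labels) {
  truth <- lapply(split(seq_along(labels), labels), sort)
  leaves <- lapply(tree_leaves(tree), function(nd) sort(nd$cases))
  ka <- sort(unname(vapply(leaves, paste, character(1), collapse = ",")))
  kb <- sort(unname(vapply(truth, paste, character(1), collapse = ",")))
  expect_equal(ka, kb)
}
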