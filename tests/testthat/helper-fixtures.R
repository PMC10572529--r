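# Shared generators for random test instances.

# Random normalized profile over a subset of a network's nodes; a share
# of zeros is planted so the c = 0 conventions get exercised.
rnd_profile <- function(net, seed, coverage = 1, p_zero = 0.15) {
  withr::with_seed(seed, {
    n <- length(net$nodes)
    covered <- sort(sample(net$nodes, max(1L, round(coverage * n))))
    cv <- stats::runif(length(covered))
    cv[stats::runif(length(covered)) < p_zero] <- 0
    structure(list(sample_id = paste0("rnd", seed),
                   c = stats::setNames(cv, covered)),
              class = "expression_profile")
  })
}

# Write a small expression matrix to a temp file and return the path.
write_expr_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Fully seeded random (network, profile) test instance.
rnd_instance <- function(seed, n_range = 2:20, p_range = c(0.05, 0.95),
                         cov_range = c(0.2, 1)) {
  pars <- withr::with_seed(seed * 3 + 1, list(
    n = sample(n_range, 1L),
    p = stats::runif(1, p_range[1], p_range[2]),
    cov = stats::runif(1, cov_range[1], cov_range[2])))
  net <- random_network(pars$n, pars$p, seed = seed * 3 + 2)
  prof <- rnd_profile(net, seed * 3 + 3, coverage = pars$cov)
  list(net = net, prof = prof)
}

# Seeded random network with randomized size and density.
rnd_net <- function(seed, n_range = 2:12, p_range = c(0, 1)) {
  pars <- withr::with_seed(seed * 5 + 1, list(
    n = sample(n_range, 1L),
    p = stats::runif(1, p_range[1], p_range[2])))
  random_network(pars$n, pars$p, seed = seed * 5 + 2)
}

kgml_minimal <- function(entries, relations) {
  paste0(
    '<?xml version="1.0"?><pathway name="path:test" org="hsa" title="test">',
    paste(entries, collapse = ""), paste(relations, collapse = ""),
    "</pathway>"
  )
}
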