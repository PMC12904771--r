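test_that("LG transition matrix is stochastic, exact at t = 0, ergodic", {
  expect_equal(lg_transition_matrix(0), diag(20), tolerance = 1e-9,
               ignore_attr = TRUE)
  p1 <- lg_transition_matrix(1)
  expect_true(all(abs(rowSums(p1) - 1) < 1e-12))
  expect_error(lg_transition_matrix(-0.1), ">= 0")

  # normalized generator: expected substitutions per site per unit t is 1
  pi <- lg_frequencies()
  q <- divorph:::lg_generator()
  expect_equal(-sum(pi * diag(q)), 1, tolerance = 1e-12)

  # long-time convergence to the equilibrium frequencies
  p_inf <- lg_transition_matrix(100)
  expect_true(max(abs(sweep(p_inf, 2, pi))) < 1e-6)
})

test_that("embedded LG constants match an independent source", {
  skip_if_not_installed("phangorn")
  s <- matrix(0, 20, 20)
  s[upper.tri(s)] <- divorph:::.lg_exchangeabilities
  s <- s + t(s)
  ref <- utils::getFromNamespace(".LG", "phangorn")
  expect_equal(s[lower.tri(s)], ref$Q, tolerance = 1e-8)
  expect_equal(unname(lg_frequencies()), unname(ref$bf / sum(ref$bf)),
               tolerance = 1e-5)
})

test_that("site rates follow the invariant + gamma law", {
  set.seed(1)
  r <- draw_site_rates(1e5, alpha = 0.1, p_inv = 0)
  # mean 1 within 3 SE; variance 1/alpha within sampling error
  se_mean <- sqrt(10 / 1e5)
  expect_lt(abs(mean(r) - 1), 3 * se_mean)
  se_var <- sqrt((3 + 6 / 0.1 - 1) * 10^2 / 1e5)
  expect_lt(abs(var(r) - 10), 3 * se_var)

  r2 <- draw_site_rates(1e4, alpha = 0.5, p_inv = 0.3)
  expect_equal(mean(r2 == 0), 0.3, tolerance = 0.05)
  expect_error(draw_site_rates(10, alpha = 0), "> 0")

  # p_inv = 1 limit: all invariant
  expect_true(all(draw_site_rates(100, 1, p_inv = 1) == 0))
})

test_that("evolve_branch: t = 0 identity, invariant sites immutable", {
  set.seed(2)
  codes <- divorph:::seq_to_int(random_records(1, 200, 200)$sequence)
  rates <- draw_site_rates(length(codes), 0.5)
  par <- evolution_params(alpha = 0.5, ins_rate = 0.01, del_rate = 0.01)
  st0 <- evolve_branch(codes, rates, 0, par)
  expect_identical(st0$codes, codes)

  rates_inv <- rep(0, length(codes))
  st <- evolve_branch(codes, rates_inv, 5, evolution_params(alpha = 0.5))
  expect_identical(st$codes, codes)
  expect_error(evolve_branch(integer(0), numeric(0), 1,
                             evolution_params()), "empty")
})

test_that("per-site substitution fraction matches the closed form at t = 1", {
  # all rates fixed at 1, no indels: P(site differs) = 1 - P[x, x](1)
  set.seed(4)
  n <- 10000
  pi <- lg_frequencies()
  codes <- sample.int(20L, n, replace = TRUE, prob = pi)
  p1 <- lg_transition_matrix(1)
  expected <- mean(1 - diag(p1)[codes])
  st <- evolve_branch(codes, rep(1, n), 1, evolution_params(alpha = 1))
  observed <- mean(st$codes != codes)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(observed - expected), 3 * se)
})

test_that("no-indel mode preserves length exactly; indels change it", {
  set.seed(5)
  root <- random_records(1, 80, 80)
  tree <- default_tree()
  fam <- evolve_tree(root, tree, evolution_params(alpha = 1, seed = 11))
  expect_setequal(fam$descendants$taxon_label, paste0("Taxon", 1:4))
  expect_true(all(nchar(fam$descendants$sequence) == 80))
  expect_true(all(fam$events$n_ins == 0 & fam$events$n_del == 0))

  fam2 <- evolve_tree(root, tree,
                      evolution_params(alpha = 1, ins_rate = 0.02,
                                       del_rate = 0.02, seed = 11))
  expect_gt(sum(fam2$events$n_ins + fam2$events$n_del), 0)
})

test_that("evolve_tree is byte-reproducible under a fixed seed", {
  root <- random_records(1, 60, 60, seed = 9)
  par <- evolution_params(alpha = 0.3, ins_rate = 0.01, del_rate = 0.01,
                          seed = 77)
  f1 <- evolve_tree(root, default_tree(), par)
  f2 <- evolve_tree(root, default_tree(), par)
  expect_identical(f1$descendants, f2$descendants)
  expect_identical(f1$events, f2$events)
})

test_that("realized substitution counts scale linearly with path length", {
  set.seed(6)
  root <- random_records(1, 150, 150)
  tree <- default_tree()
  sims <- lapply(1:60, function(i)
    evolve_tree(root, tree, evolution_params(alpha = 1))$events)
  n_sub <- Reduce(`+`, lapply(sims, `[[`, "n_sub")) / length(sims)
  path <- sims[[1]]$path_length  # terminal + inner 0.1 edges above each tip
  expect_equal(path, c(1.2, 3.2, 5.1, 10.0))
  ratio <- n_sub / (150 * path)
  # Poisson(rate * t) thinning: events per site per unit length ~ mean rate 1
  expect_true(all(abs(ratio - 1) < 0.2))
})

test_that("short branches keep higher identity to the root than long ones", {
  set.seed(7)
  tree <- default_tree()
  wins <- 0L
  n_fam <- 200
  for (i in seq_len(n_fam)) {
    root <- random_records(1, 60, 60, prefix = sprintf("r%d_", i))
    fam <- evolve_tree(root, tree, evolution_params(alpha = 1))
    d <- fam$descendants
    ident <- function(taxon) {
      a <- strsplit(root$sequence, "")[[1]]
      b <- strsplit(d$sequence[d$taxon_label == taxon], "")[[1]]
      mean(a == b)
    }
    if (ident("Taxon1") > ident("Taxon4")) wins <- wins + 1L
  }
  expect_gte(wins / n_fam, 0.95)
})
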