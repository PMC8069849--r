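# Posterior inference in both marginalization modes, ordered evidence and
# information gain.

test_that("classical posteriors match hand Bayes on the bat fixture", {
  net <- bat_network()
  post <- posterior(net, "habitat",
                    evidence(riparian = "present", woodland = "present"))
  expect_equal(unname(post$distribution), c(0.9, 0.1), tolerance = 1e-12)

  # diagnostic direction: P(riparian | habitat good) by hand Bayes
  # P(good) = 0.1*0.5*0.9 + 0.9*0.5*0.3 + 0.1*0.5*0.6 + 0.9*0.5*0.05
  p_good <- 0.1 * 0.5 * 0.9 + 0.9 * 0.5 * 0.3 + 0.1 * 0.5 * 0.6 + 0.9 * 0.5 * 0.05
  p_rip_and_good <- 0.1 * 0.5 * 0.9 + 0.1 * 0.5 * 0.6
  post <- posterior(net, "riparian", evidence(habitat = "good"))
  expect_equal(unname(post$distribution[["present"]]), p_rip_and_good / p_good,
               tolerance = 1e-12)

  # no evidence, query a root: the prior
  expect_equal(unname(posterior(net, "riparian")$distribution), c(0.1, 0.9),
               tolerance = 1e-12)

  # returned distributions are normalized
  expect_equal(sum(post$distribution), 1, tolerance = 1e-9)

  expect_error(posterior(net, "habitat", evidence(habitat = "good")), "query")
  # zero-probability evidence is a measurement error
  degen <- qbn(qnode("A", c("t", "f"), probs = c(1, 0)),
               qnode("B", c("t", "f"), parents = "A",
                     probs = rbind(c(0.5, 0.5), c(0.5, 0.5))))
  expect_error(posterior(degen, "B", evidence(A = "f")), "zero")
})

test_that("both modes agree with the brute-force enumeration oracle", {
  set.seed(11)
  for (i in 1:30) {
    net <- random_network(sample(2:4, 1), phase = sample(c("zero", "random"), 1))
    query <- sample(names(net$nodes), 1)
    others <- setdiff(names(net$nodes), query)
    ev <- NULL
    if (length(others) > 0 && runif(1) < 0.6) {
      nd <- sample(others, 1)
      ev <- stats::setNames(sample(net$nodes[[nd]]$states, 1), nd)
    }
    ok <- TRUE
    post_c <- tryCatch(posterior(net, query, ev, mode = "classical"),
                       error = function(e) { ok <<- FALSE; NULL })
    if (!ok) next  # zero-probability evidence drawn
    post_q <- posterior(net, query, ev, mode = "coherent")
    expect_equal(unname(post_c$distribution),
                 unname(oracle_posterior(net, query, ev, "classical")),
                 tolerance = 1e-10)
    expect_equal(unname(post_q$distribution),
                 unname(oracle_posterior(net, query, ev, "coherent")),
                 tolerance = 1e-10)
    # decomposition identity per query state
    expect_equal(post_q$interference$coherent_probability,
                 post_q$interference$classical_sum +
                   post_q$interference$interference_term,
                 tolerance = 1e-12)
  }
})

test_that("hidden parent paths interfere in coherent mode (collider)", {
  # two root causes, phases pi apart on the second root, common child
  net <- qbn(
    qnode("A", c("t", "f"), probs = c(0.5, 0.5)),
    qnode("B", c("t", "f"), probs = c(0.5, 0.5), phases = rbind(c(0, pi))),
    qnode("C", c("t", "f"), parents = c("A", "B"),
          probs = rbind(c(0.8, 0.2), c(0.4, 0.6), c(0.3, 0.7), c(0.9, 0.1)))
  )
  post_q <- posterior(net, "C", mode = "coherent")
  post_c <- posterior(net, "C", mode = "classical")
  expect_equal(unname(post_q$distribution),
               unname(oracle_posterior(net, "C", mode = "coherent")),
               tolerance = 1e-10)
  gap <- max(abs(post_q$distribution - post_c$distribution))
  expect_gt(gap, 0.01)
  expect_gt(max(abs(post_q$interference$interference_term)), 0.01)
})

test_that("coherent marginalization is classical when cross terms cancel", {
  # two equally likely hidden branches pi/2 apart: the interference term of
  # the summed pair vanishes and the coherent posterior matches classical
  net <- qbn(
    qnode("H", c("h1", "h2"), probs = c(0.5, 0.5), phases = rbind(c(0, pi / 2))),
    qnode("Y", c("t", "f"), parents = "H",
          probs = rbind(c(0.7, 0.3), c(0.7, 0.3)))
  )
  post_q <- posterior(net, "Y", mode = "coherent")
  post_c <- posterior(net, "Y", mode = "classical")
  expect_equal(post_q$distribution, post_c$distribution, tolerance = 1e-12)
  expect_lt(max(abs(post_q$interference$interference_term)), 1e-12)

  # single contributing history per query state: modes agree for any phases
  id <- rbind(c(1, 0), c(0, 1))
  det <- qbn(qnode("A", c("t", "f"), probs = c(0.3, 0.7),
                   phases = rbind(c(1.2, 0.4))),
             qnode("B", c("t", "f"), parents = "A", probs = id,
                   phases = rbind(c(0.9, 0), c(0, 2.2))))
  expect_equal(posterior(det, "B", mode = "coherent")$distribution,
               posterior(det, "B", mode = "classical")$distribution,
               tolerance = 1e-12)
})

test_that("unrotated ordered evidence is order-invariant and classical", {
  set.seed(12)
  for (i in 1:15) {
    net <- random_network(3, phase = "random")
    nodes <- names(net$nodes)
    ev_nodes <- sample(nodes, 2)
    states <- vapply(ev_nodes, function(n) sample(net$nodes[[n]]$states, 1),
                     character(1))
    e12 <- do.call(evidence, as.list(stats::setNames(states, ev_nodes)))
    e21 <- do.call(evidence, as.list(stats::setNames(rev(states), rev(ev_nodes))))
    psi12 <- tryCatch(sequential_condition(net, e12), error = function(e) NULL)
    if (is.null(psi12)) next  # impossible evidence drawn
    psi21 <- sequential_condition(net, e21)
    expect_equal(psi12$amp, psi21$amp, tolerance = 1e-12)
  }

  # a single unrotated finding reproduces the classical posterior
  net <- chain_net()
  psi <- sequential_condition(net, evidence(A = "a1"))
  expect_equal(marginal_distribution(psi, "B"),
               posterior(net, "B", evidence(A = "a1"))$distribution,
               tolerance = 1e-12)
})

test_that("rotated-basis findings make evidence order matter", {
  # hand oracle: psi(a,b) = amp(a) * amp(b|a); a 45-degree finding on B is
  # uncertain evidence u = (cos phi, sin phi), applied by revising B's
  # marginal amplitude to u while preserving the L2-normalized conditional
  # slices; an A finding is an ordinary projection.
  pa <- c(0.3, 0.7)
  pb <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  phi <- pi / 4
  net <- chain_net(pa, pb, rotation_b = phi)
  u <- c(cos(phi), sin(phi))
  psi_ab <- sqrt(pa) %o% c(1, 1) * sqrt(pb)   # 2x2, rows a, cols b

  # order 1: A=a1 first, then B=b1 in the rotated basis
  s1 <- psi_ab[1, ] / sqrt(sum(psi_ab[1, ]^2))       # collapse on a1
  o1 <- u * 1                                         # slices are unit scalars
  o1_marg <- o1^2 / sum(o1^2)

  # order 2: B=b1 rotated first, then A=a1
  col_norm <- sqrt(colSums(psi_ab^2))
  psi2 <- sweep(psi_ab, 2, col_norm, "/") * rep(u, each = 2)
  psi2 <- psi2[1, ]                                   # collapse on a1
  o2_marg <- psi2^2 / sum(psi2^2)

  m1 <- marginal_distribution(
    sequential_condition(net, evidence(A = "a1", B = "b1")), "B")
  m2 <- marginal_distribution(
    sequential_condition(net, evidence(B = "b1", A = "a1")), "B")
  expect_equal(unname(m1), o1_marg, tolerance = 1e-12)
  expect_equal(unname(m2), o2_marg, tolerance = 1e-12)
  expect_gt(max(abs(m1 - m2)), 0.01)

  # rotation 0 restores order invariance on the same network
  net0 <- chain_net(pa, pb, rotation_b = 0)
  m1 <- marginal_distribution(
    sequential_condition(net0, evidence(A = "a1", B = "b1")), "B")
  m2 <- marginal_distribution(
    sequential_condition(net0, evidence(B = "b1", A = "a1")), "B")
  expect_equal(m1, m2, tolerance = 1e-12)

  # impossible finding names the step
  degen <- qbn(qnode("A", c("t", "f"), probs = c(1, 0)),
               qnode("B", c("t", "f"), parents = "A",
                     probs = rbind(c(0.5, 0.5), c(0.5, 0.5))))
  expect_error(sequential_condition(degen, evidence(B = "t", A = "f")),
               "finding 2")
})

test_that("roshambo is solution-incomplete for single findings", {
  net <- roshambo_network()
  for (nd in c("p1", "p2")) {
    for (st in c("rock", "paper", "scissors")) {
      expect_equal(information_gain(net, stats::setNames(st, nd), "outcome"), 0)
    }
  }
  # an isolated node carries no information either
  iso <- qbn(qnode("A", c("t", "f"), probs = c(0.4, 0.6)),
             qnode("Z", c("u", "v"), probs = c(0.5, 0.5)))
  expect_equal(information_gain(iso, c(Z = "u"), "A"), 0, tolerance = 1e-12)

  # both moves specified: deterministic outcome in all 9 games
  beats <- c(rock = "scissors", paper = "rock", scissors = "paper")
  for (m1 in names(beats)) for (m2 in names(beats)) {
    post <- posterior(net, "outcome", evidence(p1 = m1, p2 = m2))$distribution
    winner <- if (m1 == m2) "draw" else if (beats[[m1]] == m2) "p1_wins" else "p2_wins"
    expect_equal(unname(post[[winner]]), 1)
  }
})

test_that("evidence construction enforces ordering rules", {
  ev <- evidence(riparian = "present", woodland = "absent")
  expect_equal(ev$node, c("riparian", "woodland"))
  expect_error(evidence(a = "x", a = "y"), "at most once")
  expect_error(evidence("x"), "named")
  net <- bat_network()
  expect_error(posterior(net, "habitat", evidence(nope = "x")), "unknown")
  expect_error(posterior(net, "habitat", evidence(riparian = "nope")), "no state")
})
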