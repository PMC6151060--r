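test_that("biosynthetic support hits its bounds and hand-computed values", {
  host_A <- net_from_edges("A>X")
  expect_equal(biosynthetic_support(seed_set_of("m", A = 1), host_A)$value, 1)
  host_none <- net_from_edges("Y>Z")
  expect_equal(
    biosynthetic_support(seed_set_of("m", A = 1, B = 1), host_none)$value, 0
  )
  # weighted (0.5 + 1.0) / 2 = 0.75; unweighted 2/3
  focal <- seed_set_of("m", A = 0.5, B = 0.5, C = 1.0)
  host <- net_from_edges("A>X C>X", nodes = c("A", "C", "X"))
  expect_equal(biosynthetic_support(focal, host)$value, 0.75)
  expect_equal(biosynthetic_support(focal, host, weighted = FALSE)$value,
               2 / 3)
  expect_error(biosynthetic_support(seed_set_of("m"), host), "empty")
})

test_that("complementarity excludes the partner's own feed", {
  nwA <- net_from_edges("A>B")
  sA <- detect_seeds(nwA)
  # identical organisms: every shared compound is the partner's seed too
  expect_equal(complementarity(sA, nwA, sA)$value, 0)
  # focal seeds {A,B}; partner nodes {A,B,C}, partner seed {B}: 1/2
  focal <- seed_set_of("f", A = 1, B = 1)
  partner_nw <- net_from_edges("B>A B>C", organism_id = "p")
  partner_seeds <- detect_seeds(partner_nw)
  expect_equal(seed_ids(partner_seeds), "B")
  expect_equal(complementarity(focal, partner_nw, partner_seeds)$value, 0.5)
  expect_equal(
    complementarity(focal, partner_nw, partner_seeds,
                    weighted = FALSE)$value, 0.5
  )
})

test_that("competition measures seed overlap and is asymmetric", {
  a <- seed_set_of("a", A = 1, B = 1, C = 1)
  expect_equal(competition(a, a)$value, 1)
  b <- seed_set_of("b", X = 1, Y = 1)
  expect_equal(competition(a, b)$value, 0)
  c <- seed_set_of("c", A = 1, X = 1)
  expect_equal(competition(a, c)$value, 1 / 3)
  expect_equal(competition(c, a)$value, 1 / 2)
})

test_that("planted community overlap is recovered exactly", {
  ov <- matrix(0, 2, 2)
  ov[1, 2] <- ov[2, 1] <- 0.4
  cm <- generate_community(2, 10, ov, rng_seed = 31)
  s1 <- cm$community[[1]]$seeds
  s2 <- cm$community[[2]]$seeds
  expect_equal(competition(s1, s2)$value, 0.4)
  expect_equal(competition(s2, s1)$value, 0.4)
})

test_that("pairwise matrices agree with single-pair calls and diagonal contracts", {
  ov <- matrix(c(0, .4, .2, .4, 0, .1, .2, .1, 0), 3, 3)
  ct <- matrix(0, 3, 3); ct[1, 2] <- 0.3; ct[3, 1] <- 0.2
  cm <- generate_community(3, 10, ov, complementarity_targets = ct,
                           rng_seed = 17)
  mats <- pairwise_matrices(cm$community)
  expect_equal(dim(mats$competition), c(3, 3))
  expect_equal(unname(diag(mats$competition)), rep(1, 3))
  expect_equal(unname(diag(mats$complementarity)), rep(0, 3))
  for (i in 1:3) {
    for (j in 1:3) {
      expect_equal(
        mats$competition[i, j],
        competition(cm$community[[i]]$seeds,
                    cm$community[[j]]$seeds)$value
      )
      expect_equal(
        mats$complementarity[i, j],
        complementarity(cm$community[[i]]$seeds,
                        cm$community[[j]]$network,
                        cm$community[[j]]$seeds)$value
      )
    }
  }
  expect_equal(unname(mats$competition), unname(cm$manifest$competition))
  expect_equal(unname(mats$complementarity),
               unname(cm$manifest$complementarity))
})

test_that("identical organisms give full competition and zero complementarity", {
  nw1 <- net_from_edges("A>B B>C", organism_id = "o1")
  nw2 <- net_from_edges("A>B B>C", organism_id = "o2")
  cm <- build_community(list(nw1, nw2))
  mats <- pairwise_matrices(cm)
  expect_true(all(mats$competition == 1))
  expect_true(all(mats$complementarity == 0))
  dup <- build_community(list(nw1, nw1))
  expect_error(pairwise_matrices(dup), "Duplicate")
})

test_that("weighted complementarity + competition partition the seeds found in the partner", {
  withr::local_seed(606)
  for (rep in 1:10) {
    a <- random_digraph(sample(10:40, 1), 0.08, organism_id = "a")
    b <- random_digraph(sample(10:40, 1), 0.08, organism_id = "b")
    # overlap the namespaces so the indices are non-trivial
    swap <- sample(network_nodes(a), 5)
    names(swap) <- sample(network_nodes(b), 5)
    b_edges <- b$edges
    for (nm in names(swap)) {
      b_edges$from[b_edges$from == nm] <- swap[[nm]]
      b_edges$to[b_edges$to == nm] <- swap[[nm]]
    }
    b <- metabolic_network(
      b_edges,
      compounds = tibble::tibble(
        base_id = unique(c(setdiff(network_nodes(b), names(swap)),
                           unname(swap)))
      ),
      organism_id = "b"
    )
    sa <- detect_seeds(a); sb <- detect_seeds(b)
    comp <- competition(sa, sb)$value
    compl <- complementarity(sa, b, sb)$value
    in_partner <- biosynthetic_support(sa, b)$value
    expect_equal(comp + compl, in_partner, tolerance = 1e-12)
    # own-network support is exact
    expect_equal(biosynthetic_support(sa, a)$value, 1)
    expect_true(all(c(comp, compl, in_partner) >= 0 &
                      c(comp, compl, in_partner) <= 1))
  }
})

test_that("nested networks score parasite-like, alien networks commensal-like", {
  # microbe fully nested in the host: all seeds are host nodes
  microbe <- net_from_edges("A>B B>C", organism_id = "nested")
  host <- net_from_edges("A>B B>C C>D D>E H>A", organism_id = "host")
  s <- biosynthetic_support(detect_seeds(microbe), host)$value
  expect_gt(s, 0.75)
  alien <- net_from_edges("Q>R R>S", organism_id = "alien")
  s_alien <- biosynthetic_support(detect_seeds(alien), host)$value
  expect_lt(s_alien, 0.75)
})

test_that("weighted and unweighted variants coincide for singleton seed components", {
  cm <- generate_community(2, 8, matrix(c(0, .25, .25, 0), 2, 2),
                           rng_seed = 9)
  s1 <- cm$community[[1]]$seeds
  s2 <- cm$community[[2]]$seeds
  expect_equal(competition(s1, s2)$value,
               competition(s1, s2, weighted = FALSE)$value)
  expect_equal(
    complementarity(s1, cm$community[[2]]$network, s2)$value,
    complementarity(s1, cm$community[[2]]$network, s2,
                    weighted = FALSE)$value
  )
})

test_that("interaction matrices tidy into long format and write stable TSVs", {
  cm <- generate_community(2, 10, matrix(c(0, .4, .4, 0), 2, 2),
                           rng_seed = 3)
  host <- net_from_edges("A>B", organism_id = "host")
  mats <- pairwise_matrices(cm$community, host = host)
  long <- tidy(mats)
  expect_setequal(unique(long$kind),
                  c("competition", "complementarity", "support"))
  expect_equal(nrow(long), 4 + 4 + 2)
  dir <- withr::local_tempdir()
  paths <- write_interaction_matrices(mats, dir)
  expect_length(paths, 3)
  first <- readLines(paths[1])
  expect_match(first[1], "focal=row partner=column")
})
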