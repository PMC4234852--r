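test_that("an unmodified, enzyme-free array enables only initiation and background acetylation", {
  m <- spread_model(n = 50, mechanism = "diffusion")
  s <- initial_state(m, "all_U_empty")
  ch <- enumerate_reactions(s, m)
  expect_setequal(unique(ch$kind), c("initiate", "background_acetylate"))
  expect_equal(sum(ch$kind == "initiate"), 1)
  expect_equal(sum(ch$kind == "background_acetylate"), 50)
  expect_equal(sum(ch$propensity), 2.4 + 50 * 2.4)
})

test_that("a saturated methylated array leaves only unbinding and demodification", {
  m <- spread_model(n = 50, mechanism = "combined")
  s <- initial_state(m, "all_M_occupied")
  ch <- enumerate_reactions(s, m)
  expect_setequal(unique(ch$kind), c("unbind", "demodify"))
  expect_equal(sum(ch$kind == "unbind"), 50)
  expect_equal(sum(ch$kind == "demodify"), 50)
})

test_that("mechanism gating controls which movement channels exist", {
  s <- array_state(c("U", "M", "U", "U"), c("empty", "Mt", "empty", "empty"))
  m_diff <- spread_model(n = 4, mechanism = "diffusion",
                         initiation_sites = c(Mt = 1))
  m_recr <- spread_model(n = 4, mechanism = "recruitment",
                         initiation_sites = c(Mt = 1))
  m_comb <- spread_model(n = 4, mechanism = "combined",
                         initiation_sites = c(Mt = 1))
  k_diff <- enumerate_reactions(s, m_diff)$kind
  k_recr <- enumerate_reactions(s, m_recr)$kind
  k_comb <- enumerate_reactions(s, m_comb)$kind
  expect_true("slide" %in% k_diff)
  expect_false(any(c("catalyze_neighbor", "recruit") %in% k_diff))
  expect_true(all(c("catalyze_neighbor") %in% k_recr))
  expect_false("slide" %in% k_recr)
  expect_true(all(c("slide", "catalyze_neighbor") %in% k_comb))
})

test_that("slide channels split the total hop rate and respect reflective boundaries", {
  m <- spread_model(n = 3, mechanism = "diffusion",
                    initiation_sites = c(Mt = 2))
  # enzyme at the left edge: only a rightward slide, at half the hop rate
  s <- array_state(rep("U", 3), c("Mt", "empty", "empty"))
  ch <- enumerate_reactions(s, m)
  slides <- ch[ch$kind == "slide", ]
  expect_equal(nrow(slides), 1)
  expect_equal(slides$pos2, 2L)
  expect_equal(slides$propensity, 0.3)
  # interior enzyme flanked by empties: both directions
  s2 <- array_state(rep("U", 3), c("empty", "Mt", "empty"))
  slides2 <- enumerate_reactions(s2, m)
  slides2 <- slides2[slides2$kind == "slide", ]
  expect_equal(sort(slides2$pos2), c(1L, 3L))
  expect_equal(sum(slides2$propensity), 0.6)
  # blocked by a neighbouring enzyme: enzymes cannot pass each other
  s3 <- array_state(rep("U", 3), c("Mt", "Mt", "empty"))
  slides3 <- enumerate_reactions(s3, m)
  slides3 <- slides3[slides3$kind == "slide", ]
  expect_equal(nrow(slides3), 1)
  expect_equal(slides3$pos1, 2L)
})

test_that("channel enumeration matches the naive clause-by-clause oracle on random states", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(2:8, 1)
    m <- random_small_model(n)
    for (j in 1:20) {
      s <- random_state(m)
      got <- canonical_channels(enumerate_reactions(s, m))
      want <- canonical_channels(naive_channels(s, m))
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$kind, want$kind)
      expect_equal(got$enzyme, want$enzyme)
      expect_equal(got$pos1, want$pos1)
      expect_equal(got$pos2, want$pos2)
      expect_equal(got$propensity, want$propensity, tolerance = 1e-12)
    }
  }
})

test_that("applying reactions updates exactly the named positions and preserves invariants", {
  s <- array_state(c("U", "U", "M", "U"), c("empty", "empty", "Mt", "empty"))
  # slide moves the enzyme, marks untouched
  s2 <- apply_reaction(s, list(kind = "slide", enzyme = "Mt", pos1 = 3,
                               pos2 = 4))
  expect_equal(s2$occ, c("empty", "empty", "empty", "Mt"))
  expect_equal(s2$mod, s$mod)
  # connect with two enzymes exchanges them, marks untouched
  sd <- array_state(c("M", "U", "A", "U"), c("Mt", "empty", "At", "empty"))
  sd2 <- apply_reaction(sd, list(kind = "connect", enzyme = "none", pos1 = 1,
                                 pos2 = 3))
  expect_equal(sd2$occ, c("At", "empty", "Mt", "empty"))
  expect_equal(sd2$mod, sd$mod)
  # connect with one enzyme hops it across
  sh <- apply_reaction(s, list(kind = "connect", enzyme = "none", pos1 = 3,
                               pos2 = 1))
  expect_equal(sh$occ, c("Mt", "empty", "empty", "empty"))
  # demodification clears the mark, occupancy untouched
  s3 <- apply_reaction(s, list(kind = "demodify", enzyme = "none", pos1 = 3,
                               pos2 = NA))
  expect_equal(s3$mod[3], "U")
  expect_equal(s3$occ, s$occ)
})

test_that("applying a non-enabled reaction is detected", {
  s <- array_state(c("U", "U"), c("Mt", "Mt"))
  expect_error(apply_reaction(s, list(kind = "slide", enzyme = "Mt",
                                      pos1 = 1, pos2 = 2)),
               class = "nucspread_logic_error")
  expect_error(apply_reaction(s, list(kind = "recruit", enzyme = "Mt",
                                      pos1 = 1, pos2 = NA)),
               class = "nucspread_logic_error")
  expect_error(apply_reaction(s, list(kind = "demodify", enzyme = "none",
                                      pos1 = 1, pos2 = NA)),
               class = "nucspread_logic_error")
})

test_that("closure: firing any enabled channel yields a valid state", {
  set.seed(202)
  for (rep in 1:25) {
    m <- random_small_model(sample(2:6, 1))
    s <- random_state(m)
    ch <- enumerate_reactions(s, m)
    for (r in seq_len(nrow(ch))) {
      s2 <- apply_reaction(s, ch[r, ], check = TRUE)
      expect_s3_class(s2, "array_state")  # constructor enforces invariants
      changed <- which(s2$mod != s$mod | s2$occ != s$occ)
      expect_true(all(changed %in% stats::na.omit(c(ch$pos1[r], ch$pos2[r]))))
    }
  }
})

test_that("initial-state presets match their definitions", {
  m <- spread_model(n = 50, mechanism = "combined")
  all_m <- initial_state(m, "all_M_occupied")
  expect_true(all(all_m$mod == "M") && all(all_m$occ == "Mt"))
  all_a <- initial_state(m, "all_A_empty")
  expect_true(all(all_a$mod == "A") && all(all_a$occ == "empty"))
  s1 <- initial_state(m, "k_seeds", k = 1)
  expect_equal(which(s1$mod == "M"), 25L)
  expect_equal(which(s1$occ == "Mt"), 25L)
  expect_true(all(s1$mod[-25] == "U"))
  expect_equal(seed_positions(50, 2), c(13L, 38L))
  expect_equal(seed_positions(50, 5), c(5L, 15L, 25L, 35L, 45L))
  s50 <- initial_state(m, "k_seeds", k = 50)
  expect_true(all(s50$mod == "M") && all(s50$occ == "Mt"))
  expect_error(initial_state(m, "k_seeds", k = 51),
               class = "nucspread_config_error")
})

test_that("model validation rejects inconsistent configurations", {
  expect_error(spread_model(n = 1), class = "nucspread_config_error")
  expect_error(spread_model(initiation_sites = c(Mt = 99)),
               class = "nucspread_config_error")
  expect_error(spread_model(initiation_sites = c(At = 10)),
               class = "nucspread_config_error")  # At needs a dual model
  expect_error(spread_model(enzymes = "dual",
                            initiation_sites = c(Mt = 5, At = 5)),
               class = "nucspread_config_error")
  expect_error(spread_model(connectivity_sites = c(10, 10, 20)),
               class = "nucspread_config_error")
  expect_error(spread_rates(k_off = -1), class = "nucspread_config_error")
  expect_error(check_state <- enumerate_reactions(
    array_state(rep("U", 5), rep("empty", 5)), spread_model(n = 6)),
    class = "nucspread_config_error")
  # dual default k_on is the low two-enzyme value
  expect_equal(spread_model(enzymes = "dual")$rates$k_on, 0.01)
  expect_equal(spread_model()$rates$k_on, 2.4)
})

test_that("connectivity layouts are the bundled equidistant site sets", {
  expect_equal(connectivity_layout(2), c(15L, 35L))
  expect_equal(connectivity_layout(3), c(12L, 25L, 38L))
  expect_equal(connectivity_layout(5), c(8L, 16L, 25L, 34L, 42L))
  expect_equal(connectivity_layout(10), seq(3L, 48L, by = 5L))
  expect_error(connectivity_layout(4), class = "nucspread_config_error")
  m <- spread_model(enzymes = "dual", connectivity_sites = 10)
  expect_length(m$connectivity_sites, 10)
})
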