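identity_map <- function(len = 10000L) {
  offset_map(tibble::tibble(a_start = 1L, a_end = len, b_start = 1L,
                            b_end = len, orientation = "+"))
}

test_that("coordinate mapping handles shifts, orientation, and gaps", {
  m <- identity_map()
  expect_equal(map_coordinates(m, 100, 160)[, c("start", "end")],
               tibble::tibble(start = 100L, end = 160L))
  shift <- offset_map(tibble::tibble(a_start = 1L, a_end = 1000L,
                                     b_start = 8L, b_end = 1007L,
                                     orientation = "+"))
  expect_equal(map_coordinates(shift, 100, 160)[, c("start", "end")],
               tibble::tibble(start = 107L, end = 167L))
  expect_equal(nrow(map_coordinates(shift, 1500, 1560)), 0)
  # reverse block: positions flip within the block
  rev <- offset_map(tibble::tibble(a_start = 1L, a_end = 100L,
                                   b_start = 201L, b_end = 300L,
                                   orientation = "-"))
  out <- map_coordinates(rev, 1, 10)
  expect_equal(out$start, 291L)
  expect_equal(out$end, 300L)
  expect_true(out$flipped)
  # straddling two blocks: larger share wins, flagged
  two <- offset_map(tibble::tibble(a_start = c(1L, 101L), a_end = c(100L, 200L),
                                   b_start = c(1L, 151L), b_end = c(100L, 250L),
                                   orientation = "+"))
  out2 <- map_coordinates(two, 91, 130)
  expect_true(out2$straddle)
  expect_equal(out2$start, 141L)   # mapped via the 101..200 block (+50)
  # below the coverage threshold: unmappable
  expect_equal(nrow(map_coordinates(two, 95, 210, min_cover = 0.9)), 0)
})

test_that("the 15-nt rule is applied at the boundary after mapping", {
  a <- make_srna_tbl(100, 160, "+", ids = "a1")
  m <- identity_map()
  b15 <- make_srna_tbl(115, 160, "+", genome_id = "B", ids = "b1")
  expect_equal(nrow(call_conserved(a, b15, m)), 1)   # startΔ = 15: conserved
  b16 <- make_srna_tbl(116, 160, "+", genome_id = "B", ids = "b1")
  expect_equal(nrow(call_conserved(a, b16, m)), 0)   # startΔ = 16: not
  bend <- make_srna_tbl(100, 176, "+", genome_id = "B", ids = "b1")
  expect_equal(nrow(call_conserved(a, bend, m)), 0)  # endΔ = 16: not
  expect_equal(nrow(call_conserved(a, bend, m, ends = "start")), 1)
})

test_that("continuous-coverage gaps break a pair", {
  a <- make_srna_tbl(100, 160, "+", ids = "a1")
  b <- make_srna_tbl(102, 158, "+", genome_id = "B", ids = "b1")
  m <- identity_map()
  full_a <- tibble::tibble(pos = 100:160, depth = 5L)
  full_b <- tibble::tibble(pos = 102:158, depth = 5L)
  expect_equal(nrow(call_conserved(a, b, m, full_a, full_b)), 1)
  gap_b <- full_b
  gap_b$depth[20] <- 0L
  expect_equal(nrow(call_conserved(a, b, m, full_a, gap_b)), 0)
})

test_that("raising the nt threshold never removes a conserved pair", {
  set.seed(61)
  starts_a <- seq(100, 4000, by = 200)
  a <- make_srna_tbl(starts_a, starts_a + 80, "+",
                     ids = sprintf("a%02d", seq_along(starts_a)))
  starts_b <- starts_a + sample(-30:30, length(starts_a), replace = TRUE)
  b <- make_srna_tbl(starts_b, starts_b + 80 +
                       sample(-10:10, length(starts_a), replace = TRUE), "+",
                     genome_id = "B",
                     ids = sprintf("b%02d", seq_along(starts_a)))
  m <- identity_map()
  prev <- character(0)
  for (thr in c(5, 10, 15, 25, 40)) {
    pairs <- call_conserved(a, b, m, max_offset = thr)
    key <- paste(pairs$srna_a, pairs$srna_b)
    expect_true(all(prev %in% key), label = sprintf("threshold %d", thr))
    prev <- key
  }
})

test_that("pairing is symmetric under genome exchange", {
  set.seed(62)
  starts_a <- seq(100, 3000, by = 250)
  n <- length(starts_a)
  a <- make_srna_tbl(starts_a, starts_a + 70, "+",
                     ids = sprintf("a%02d", 1:n))
  b <- make_srna_tbl(starts_a + sample(-12:12, n, TRUE),
                     starts_a + 70 + sample(-12:12, n, TRUE), "+",
                     genome_id = "B", ids = sprintf("b%02d", 1:n))
  fwd <- call_conserved(a, b, identity_map())
  bwd <- call_conserved(b, a, identity_map())
  expect_equal(nrow(fwd), nrow(bwd))
  expect_setequal(paste(fwd$srna_a, fwd$srna_b),
                  paste(bwd$srna_b, bwd$srna_a))
})

test_that("greedy pairing matches brute-force minimal-offset matching", {
  m <- identity_map()
  for (rep in 1:100) {
    set.seed(700 + rep)
    n_a <- sample(3:12, 1); n_b <- sample(3:12, 1)
    sa <- sort(sample(seq(100, 5000, by = 40), n_a))
    sb <- sort(sample(seq(100, 5000, by = 40), n_b)) +
      sample(c(-12, -7, -3, 0, 3, 7, 12), n_b, replace = TRUE)
    a <- make_srna_tbl(sa, sa + 60, "+", ids = sprintf("a%02d", 1:n_a))
    b <- make_srna_tbl(sb, sb + 60, "+", genome_id = "B",
                       ids = sprintf("b%02d", 1:n_b))
    got <- call_conserved(a, b, m)
    # enumerate candidates and replay greedy selection independently
    cand <- NULL
    for (i in 1:n_a) for (j in 1:n_b) {
      ds <- abs(b$start[j] - a$start[i]); de <- abs(b$end[j] - a$end[i])
      if (ds <= 15 && de <= 15) {
        cand <- rbind(cand, data.frame(srna_a = a$srna_id[i],
                                       srna_b = b$srna_id[j],
                                       total = ds + de))
      }
    }
    want <- if (is.null(cand)) character(0) else {
      w <- oracle_greedy_pairs(cand)
      paste(w$srna_a, w$srna_b)
    }
    expect_setequal(paste(got$srna_a, got$srna_b), want)
  }
})

test_that("z-proportion test follows the stated formula", {
  # p_hat equal to p0: no signal
  null <- z_proportion_test(5, 20, 80)   # p_hat = 0.25 = p0
  expect_equal(unname(null$statistic), 0)
  expect_equal(null$p.value, 0.5)
  # hand evaluation for the Carsonella-BC style counts
  z <- z_proportion_test(11, 36, 196)
  p_hat <- 11 / 36; p0 <- 36 / 196
  expect_equal(unname(z$statistic),
               (p_hat - p0) / sqrt(p0 * (1 - p0) / 36), tolerance = 1e-12)
  expect_equal(unname(z$statistic), 1.889, tolerance = 1e-3)
  expect_equal(z$p.value, pnorm(1.8886, lower.tail = FALSE), tolerance = 1e-4)
  # zero conserved: negative z, upper-tail P above one half
  lo <- z_proportion_test(0, 10, 100)
  expect_lt(unname(lo$statistic), 0)
  expect_gt(lo$p.value, 0.5)
  expect_error(z_proportion_test(5, 10, 10), "degenerate")
})
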