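test_that("site components follow the frequency formulas", {
  c1 <- site_components(0, 1, 1, 0)
  expect_equal(c1$abba, 1)
  expect_equal(c1$baba, 0)
  # p2 = p3 makes the donor components equal the plain ones
  c2 <- site_components(0.2, 0.6, 0.6, 0.1)
  expect_equal(c2$abba_d, c2$abba)
  expect_equal(c2$baba_d, c2$baba)
  # no derived allele in P3 -> plain components vanish; the donor
  # components substitute pD = max(p2, p3) and stay positive
  c3 <- site_components(0.5, 0.5, 0, 0)
  expect_equal(c3$abba, 0)
  expect_equal(c3$baba, 0)
  expect_equal(c3$abba_d, 0.125)
  expect_error(site_components(-0.1, 0, 0, 0))
})

test_that("fd reaches 1 when P2 and P3 share all derived alleles", {
  f <- data.frame(chrom = "c", pos = seq(100, 90000, by = 100),
                  p1 = 0, p2 = 0.7, p3 = 0.7, pO = 0)
  w <- fd_windows(f, window_bp = 1e5, step_bp = 1e5, min_sites = 10)
  expect_equal(w$fd[1], 1)
})

test_that("fd is near zero under the symmetric null and NA when D <= 0", {
  f <- simulate_freq_table(20000, 2e6, seed = 1)
  w <- fd_windows(f, window_bp = 1e5, step_bp = 2e4, min_sites = 100)
  expect_lt(abs(mean(w$fd, na.rm = TRUE)), 0.05)
  # windows with non-positive D carry no defined fd
  expect_true(all(is.na(w$fd[!is.na(w$D) & w$D <= 0])))
  # windows below the site floor are NA
  w2 <- fd_windows(f[1:50, ], window_bp = 1e5, step_bp = 1e5,
                   min_sites = 100)
  expect_true(all(is.na(w2$fd)))
  expect_error(fd_windows(f[0, ], 1e5, 1e4), "empty")
  expect_error(fd_windows(f, 1e4, 1e5), "window_bp >= step_bp")
})

test_that("fd stays within [0, 1] and is invariant to site duplication", {
  f <- simulate_freq_table(
    5000, 1e6, admixed = data.frame(chrom = "chr18", start = 2e5,
                                    end = 6e5, rate = 0.7), seed = 2)
  w <- fd_windows(f, 1e5, 2e4, min_sites = 50)
  ok <- !is.na(w$fd)
  expect_true(all(w$fd[ok] >= 0 & w$fd[ok] <= 1 + 1e-9))
  dup <- rbind(f, f)
  dup <- dup[order(dup$chrom, dup$pos), ]
  w2 <- fd_windows(dup, 1e5, 2e4, min_sites = 50)
  expect_equal(w2$fd, w$fd)
})

test_that("more shared derived alleles never decrease window fd", {
  base <- data.frame(chrom = "c", pos = seq(10, 99000, by = 15),
                     pO = 0, stringsAsFactors = FALSE)
  set.seed(3)
  base$p1 <- rbeta(nrow(base), 0.5, 3)
  base$p2 <- rbeta(nrow(base), 0.5, 3)
  base$p3 <- rbeta(nrow(base), 0.8, 0.8)
  fd_at <- function(frac_shared) {
    f <- base
    n_sh <- round(frac_shared * nrow(f))
    if (n_sh) {
      f$p1[1:n_sh] <- 0
      f$p2[1:n_sh] <- 1
      f$p3[1:n_sh] <- 1
    }
    fd_windows(f, 1e5, 1e5, min_sites = 10)$fd[1]
  }
  vals <- vapply(c(0.1, 0.3, 0.5, 0.8), fd_at, 0)
  expect_true(all(diff(vals) >= -1e-9))
})

test_that("sites are repolarized against the outgroup", {
  # the same signal encoded with flipped polarity gives the same fd
  f1 <- data.frame(chrom = "c", pos = seq(100, 50000, by = 100),
                   p1 = 0.1, p2 = 0.8, p3 = 0.8, pO = 0)
  f2 <- f1
  f2[, c("p1", "p2", "p3", "pO")] <- 1 - f1[, c("p1", "p2", "p3", "pO")]
  w1 <- fd_windows(f1, 1e5, 1e5, min_sites = 10)
  w2 <- fd_windows(f2, 1e5, 1e5, min_sites = 10)
  expect_equal(w1$fd, w2$fd)
})
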