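# Independent oracles used across tests. These deliberately take naive
# brute-force routes (triple-loop enumeration, regex, full 4^w expansion) so
# they share no code path with the implementation they check.

# exhaustive enumeration of every admissible hairpin (arm start, stem, loop)
oracle_hairpin_prob <- function(win, h1, params) {
  ch <- strsplit(win, "", fixed = TRUE)[[1]]
  L <- length(ch)
  pair_ok <- function(a, b) paste0(a, b) %in% c("AT","TA","GC","CG","GT","TG")
  z_all <- 0; z_loop <- 0
  for (a in 0:(L - 1)) {
    for (s in params$min_stem:params$flank) {
      for (l in params$min_loop:params$max_loop) {
        if (a + 2 * s + l > L) next
        ok <- TRUE
        for (k in 0:(s - 1)) {
          if (!pair_ok(ch[a + k + 1], ch[a + 2 * s + l - 1 - k + 1])) {
            ok <- FALSE; break
          }
        }
        if (!ok) next
        w <- exp(params$beta * s)
        z_all <- z_all + w
        q <- a + s
        if (q <= h1 && q + l >= h1 + 6) z_loop <- z_loop + w
      }
    }
  }
  z_loop / (1 + z_all)
}

# overlapping-match regex oracle for the RIDD consensus
oracle_motif_starts <- function(seq) {
  m <- gregexpr("(?=..C.GC.G..)", seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

# scores of all 4^w windows of a PWM, on the same integer grid as the DP
oracle_pwm_enumeration <- function(pw, granularity = 1 / 1000) {
  w <- pw$width
  int_scores <- round(pw$scores / granularity)
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  ints <- rowSums(matrix(int_scores[cbind(as.vector(grid),
                                          rep(seq_len(w), each = nrow(grid)))],
                         nrow(grid), w))
  probs <- apply(matrix(pw$background[grid], nrow(grid), w), 1, prod)
  list(int = ints, prob = probs, granularity = granularity)
}

# closed-form Wilson score interval
oracle_wilson <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = centre - half, upper = centre + half)
}

random_dna <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                                collapse = "")

random_pwm <- function(width) {
  counts <- matrix(sample(0:30, 4 * width, replace = TRUE), 4, width,
                   dimnames = list(c("A","C","G","T"), NULL))
  counts[cbind(sample(1:4, width, replace = TRUE), seq_len(width))] <-
    sample(20:60, width, replace = TRUE)   # give each column a preference
  pwm(counts)
}

# a small two-gene transcript set with known UTR structure, used by several
# io/consequence tests
fixture_models <- function() {
  list(
    t1 = transcript_model("t1", "gA", strand = "+",
      exons = data.frame(start = c(100, 400), end = c(250, 700)),
      cds = data.frame(start = c(160, 400), end = c(250, 580)),
      domains = data.frame(domain = c("D1", "D2"), start = c(70, 120),
                           end = c(100, 160)),
      sequence = random_dna(450)),
    t2 = transcript_model("t2", "gA", strand = "+",
      exons = data.frame(start = c(100, 400), end = c(250, 900)),
      cds = data.frame(start = c(160, 400), end = c(250, 580)),
      domains = data.frame(domain = "D1", start = 70, end = 100),
      sequence = random_dna(650)),
    t3 = transcript_model("t3", "gB", strand = "-",
      exons = data.frame(start = c(2000, 2500), end = c(2200, 2800)),
      sequence = random_dna(500)))
}
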