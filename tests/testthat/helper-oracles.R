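# Independent brute-force oracles, kept deliberately naive and separate from
# the implementation paths they check.

aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_peptide <- function(n, id = "rand") {
  peptide(paste(sample(aa20, n, replace = TRUE), collapse = ""), id = id)
}

# Windowed profile oracle: for each position, explicitly collect the in-range
# neighbours within the half-window, sum their scale values and divide by the
# full window size (out-of-range neighbours contribute nothing).
oracle_a4v <- function(seq, scale = aggrescan_scale()) {
  chars <- strsplit(toupper(as.character(seq)), "")[[1]]
  v <- scale$a3v[chars]
  n <- length(v)
  w <- scale$window(n)
  half <- (w - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in (i - half):(i + half)) {
      if (j >= 1 && j <= n) acc <- acc + v[j]
    }
    out[i] <- acc / w
  }
  out
}

# Run-finding oracle: scan a logical vector left to right and record maximal
# TRUE runs of at least min_run.
oracle_runs <- function(hot, min_run = 5) {
  out <- data.frame(start = integer(), end = integer())
  i <- 1
  n <- length(hot)
  while (i <= n) {
    if (hot[i]) {
      j <- i
      while (j < n && hot[j + 1]) j <- j + 1
      if (j - i + 1 >= min_run) out <- rbind(out, data.frame(start = i, end = j))
      i <- j + 1
    } else i <- i + 1
  }
  out
}

# Textbook Pearson: covariance over the product of standard deviations.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Hydrophobic-moment oracle via a complex exponential sum.
oracle_mu_h <- function(seq, angle_deg = 100, scale = amylscan:::EISENBERG) {
  chars <- strsplit(toupper(as.character(seq)), "")[[1]]
  h <- scale[chars]
  k <- seq_along(h) - 1
  Mod(sum(h * exp(1i * k * angle_deg * pi / 180))) / length(h)
}

hIAPP <- iapp_sequences()$hIAPP

pep_id_test <- function(x) attr(x, "id")
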