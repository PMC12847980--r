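# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: indices are summed edge by edge over the raw bond
# list, and small OLS fits are solved from the normal equations by hand.

# per-edge brute force: loop over bonds of a graph, no partition involved
bruteIndex <- function(indexId, g, ssVariant = "sqrtRatio") {
  deg <- vertexDegrees(g)
  e <- bondMatrix(g)
  total <- 0
  for (i in seq_len(nrow(e))) {
    a <- min(deg[e[i, 1]], deg[e[i, 2]])
    b <- max(deg[e[i, 1]], deg[e[i, 2]])
    total <- total + switch(indexId,
      M1 = a + b, M2 = a * b, H = 2 / (a + b), F = a^2 + b^2,
      SS = if (ssVariant == "sqrtRatio") sqrt(a * b / (a + b))
           else 1 / (a + b)^2,
      ABC = sqrt((a + b - 2) / (a * b)), RI = 1 / sqrt(a * b),
      SC = 1 / sqrt(a + b), GA = 2 * sqrt(a * b) / (a + b),
      HZ = (a + b)^2)
  }
  total
}

# closed-form simple linear regression from the normal equations
olsOracle <- function(x, y) {
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  alpha <- mean(y) - beta * mean(x)
  list(alpha = alpha, beta = beta)
}

# cycle graph on n vertices as an edge list
cycleEdges <- function(n) cbind(seq_len(n), c(seq_len(n)[-1], 1))

studyIndexMatrix <- function() indexTable(drugPartitions())
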