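# fixtures built in code, shared across test files

# the published example chain: Class down to Group, tallgrass prairie
table1Chain <- function() {
  loadHierarchy(system.file("extdata", "ivc_table1_chain.csv",
                            package = "ecoextent"))
}

# 3-level toy forest: nClass roots, each with 2 division-like children,
# each of those with `leavesPer` leaves
toyHierarchy3 <- function(nClass = 2, leavesPer = 5) {
  rows <- data.frame(code = seq_len(nClass), name = paste0("class", seq_len(nClass)),
                     level = 1L, parent_code = NA_integer_)
  mid <- NULL; leaf <- NULL
  midCode <- 100L; leafCode <- 1000L
  for (cl in seq_len(nClass)) {
    for (m in 1:2) {
      midCode <- midCode + 1L
      mid <- rbind(mid, data.frame(code = midCode, name = paste0("mid", midCode),
                                   level = 2L, parent_code = cl))
      for (l in seq_len(leavesPer)) {
        leafCode <- leafCode + 1L
        leaf <- rbind(leaf, data.frame(code = leafCode,
                                       name = paste0("leaf", leafCode),
                                       level = 3L, parent_code = midCode))
      }
    }
  }
  loadHierarchy(rbind(rows, mid, leaf))
}

# brute-force modal code of a vector with ties to the smallest code
bruteModal <- function(x, nodata) {
  x <- x[x != nodata]
  if (!length(x)) return(nodata)
  counts <- vapply(sort(unique(x)), function(u) sum(x == u), integer(1))
  sort(unique(x))[which.max(counts)]
}

# brute-force per-code cell counts of a grid
bruteCounts <- function(grid) {
  v <- as.vector(gridCodes(grid))
  v <- v[v != nodataValue(grid)]
  out <- sapply(sort(unique(v)), function(u) sum(v == u))
  stats::setNames(as.integer(out), sort(unique(v)))
}

randomGrid <- function(nr, nc, codes, nodataFrac = 0.1, cellSize = 270) {
  spec <- GridSpec(nr, nc, cellSize = cellSize)
  v <- sample(codes, nr * nc, replace = TRUE)
  v[stats::runif(nr * nc) < nodataFrac] <- spec@nodata
  CategoricalGrid(matrix(as.integer(v), nr, nc), spec)
}
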