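# Brute-force oracles, deliberately implemented through different routes
# (igraph connectivity, dense fine-grid integration) than the package code.

# Cells reachable from a source through 4-connected paths of passable cells
# (sources are passable themselves). Returns a logical matrix.
oracle_reachable4 <- function(src, transparent) {
  passable <- src | transparent
  nr <- nrow(src); nc <- ncol(src)
  idx <- which(passable)
  if (length(idx) == 0) return(matrix(FALSE, nr, nc))
  edges <- integer(0)
  for (i in idx) {
    r <- (i - 1) %% nr + 1; c <- (i - 1) %/% nr + 1
    for (d in list(c(1, 0), c(0, 1))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 <= nr && c2 <= nc) {
        j <- (c2 - 1) * nr + r2
        if (passable[j]) edges <- c(edges, i, j)
      }
    }
  }
  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  reach_comps <- unique(comp[which(src)])
  out <- matrix(FALSE, nr, nc)
  out[passable] <- comp[which(passable)] %in% reach_comps
  out
}

# Connected-component labels of a logical matrix via igraph (4- or
# 8-connectivity). 0 = background.
oracle_label <- function(member, connectivity = 4) {
  nr <- nrow(member); nc <- ncol(member)
  idx <- which(member)
  lab <- matrix(0L, nr, nc)
  if (length(idx) == 0) return(lab)
  deltas <- list(c(1, 0), c(0, 1))
  if (connectivity == 8) deltas <- c(deltas, list(c(1, 1), c(-1, 1)))
  edges <- integer(0)
  for (i in idx) {
    r <- (i - 1) %% nr + 1; c <- (i - 1) %/% nr + 1
    for (d in deltas) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        j <- (c2 - 1) * nr + r2
        if (member[j]) edges <- c(edges, i, j)
      }
    }
  }
  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  ids <- unique(comp[idx])
  lab[idx] <- match(comp[idx], ids)
  lab
}

# Fine-grid centroid of the union of the two clipped Fall terms
# (NO = triangle 0/22.5/45, YES = triangle 35/67.5/100), by direct summation.
oracle_fall_centroid <- function(act_yes = 0, act_no = 0, step = 0.001) {
  x <- seq(0, 100, by = step)
  tri <- function(x, a, b, c) pmax(pmin((x - a) / (b - a), (c - x) / (c - b)), 0)
  mu <- pmax(pmin(tri(x, 0, 22.5, 45), act_no),
             pmin(tri(x, 35, 67.5, 100), act_yes))
  if (sum(mu) == 0) return(0)
  sum(x * mu) / sum(mu)
}

# Intersection-over-union of two (x, y, w, h) boxes.
box_jaccard <- function(a, b) {
  if (is.null(a) || is.null(b)) return(0)
  x0 <- max(a$x, b$x); y0 <- max(a$y, b$y)
  x1 <- min(a$x + a$w, b$x + b$w); y1 <- min(a$y + a$h, b$y + b$h)
  inter <- max(0, x1 - x0) * max(0, y1 - y0)
  inter / (a$w * a$h + b$w * b$h - inter)
}

# A random charge matrix mixing opaque, partially charged and saturated
# pixels, for recharge/homogenisation property tests.
random_charges <- function(nr, nc, q_max = 255) {
  vals <- sample(c(0, q_max, sample(seq_len(q_max - 1), 8, replace = TRUE)),
                 nr * nc, replace = TRUE, prob = c(0.35, 0.15, rep(0.0625, 8)))
  matrix(vals, nr, nc)
}

# Table rows used by the worked examples: final printed indicator rows of
# the backward standing fall, the lying-position fall and the kneeling
# false fall.
row_standing_backward <- data.frame(whr = 1.75, height_change = 1.40,
                                    h_vel = 0.087, v_vel = 0.610,
                                    direction = 0, position_change = 0)
row_lying <- data.frame(whr = 4.22, height_change = 1.05, h_vel = 0.000,
                        v_vel = 0.032, direction = 1, position_change = 1)
row_kneeling <- data.frame(whr = 1.92, height_change = 0.68, h_vel = 0.507,
                           v_vel = 0.282, direction = 1, position_change = 0)

all_scenarios <- c("stand_fall_frontal", "stand_fall_right",
                   "sit_fall_frontal", "sit_fall_right", "lying_fall",
                   "kneel_false", "walk_then_fall", "static_scene")
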