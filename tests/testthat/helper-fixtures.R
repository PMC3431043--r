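# Shared fixtures, all built in code at test time.

# straight tube of radius r from (x0, y, z) to (x0 + L, y, z)
cylinder_morph <- function(L = 50, r = 2, x0 = 20, y = 32, z = 32) {
  morphology(data.frame(id = 1:2, type = c(1L, 3L),
                        x = c(x0, x0 + L), y = y, z = z,
                        radius = r, parent = c(-1L, 1L)))
}

# trunk then two 25 um branches at +/- 37 deg in the xy plane
y_morph <- function() {
  morphology(data.frame(id = 1:4, type = c(1L, 3L, 3L, 3L),
                        x = c(20, 45, 65, 65), y = c(32, 32, 47, 17),
                        z = 16, radius = 2, parent = c(-1L, 1L, 2L, 2L)))
}

# random valid tree with n nodes (ids shuffled to exercise sorting)
random_tree <- function(n = 20, seed = 1, shuffle = FALSE) {
  set.seed(seed)
  id <- seq_len(n)
  parent <- c(-1L, vapply(2:n, function(i) sample(seq_len(i - 1L), 1L), integer(1)))
  nd <- data.frame(id = id, type = 3L,
                   x = cumsum(runif(n, -5, 5)) + 50,
                   y = cumsum(runif(n, -5, 5)) + 50,
                   z = cumsum(runif(n, -2, 2)) + 20,
                   radius = runif(n, 0.5, 3), parent = parent)
  nd$type[1] <- 1L
  if (shuffle) nd <- nd[sample(n), ]
  morphology(nd)
}

# bilaterally symmetric synthetic brain: two ellipsoid lobes + central body
synthetic_brain <- function(shape = c(40, 64, 96), spacing = c(2, 1, 1),
                            fg = 200, bg = 10) {
  d <- shape
  ax_z <- (seq_len(d[1]) - 1) * spacing[1]
  ax_y <- (seq_len(d[2]) - 1) * spacing[2]
  ax_x <- (seq_len(d[3]) - 1) * spacing[3]
  cx <- max(ax_x) / 2; cy <- max(ax_y) / 2; cz <- max(ax_z) / 2
  gz <- rep(ax_z, times = d[2] * d[3])
  gy <- rep(rep(ax_y, each = d[1]), times = d[3])
  gx <- rep(ax_x, each = d[1] * d[2])
  lobe <- function(x0, a, b, c_) ((gx - x0) / a)^2 + ((gy - cy) / b)^2 +
    ((gz - cz) / c_)^2 <= 1
  inside <- lobe(cx - 22, 20, 24, 28) | lobe(cx + 22, 20, 24, 28) |
    lobe(cx, 12, 10, 12)
  v <- array(bg, dim = d)
  v[array(inside, dim = d)] <- fg
  image_stack(v, spacing = spacing)
}

# the five-point alignment scheme on the synthetic brain (symmetric in x)
brain_landmarks <- function(stack) {
  ext <- stack_extent(stack)
  cx <- mean(ext[, 1]); cy <- mean(ext[, 2]); cz <- mean(ext[, 3])
  landmark_set(c("CCB", "RMC", "LMC", "RAL", "LAL"),
               x = c(cx, cx + 20, cx - 20, cx + 16, cx - 16),
               y = c(cy, cy + 12, cy + 12, cy - 14, cy - 14),
               z = c(cz, cz + 8, cz + 8, cz - 6, cz - 6))
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

rigid_from <- function(R, t) {
  structure(list(rotation = R, translation = as.numeric(t)),
            class = "rigid_transform")
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# small phantom spec for fast tracer tests
small_spec <- function(seed = 1, condition = "raw")
  phantom_spec(seed = seed, volume_shape = c(48L, 96L, 96L),
               spacing = c(2, 1, 1), segment_length = c(10, 25),
               generations = c(2L, 2L), condition = condition)
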