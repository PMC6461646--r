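# geometric fixtures built in code: digitized 2D shapes and 3D stacks

disc_mask <- function(r, pad = 10) {
  n <- 2 * r + 2 * pad + 1
  cc <- pad + r + 1
  m <- matrix(0, n, n)
  m[(row(m) - cc)^2 + (col(m) - cc)^2 <= r^2] <- 1
  m
}

square_mask <- function(s, pad = 10) {
  n <- s + 2 * pad
  m <- matrix(0, n, n)
  m[(pad + 1):(pad + s), (pad + 1):(pad + s)] <- 1
  m
}

ellipse_mask <- function(a, b, pad = 10) {
  ny <- 2 * b + 2 * pad + 1
  nx <- 2 * a + 2 * pad + 1
  m <- matrix(0, ny, nx)
  cy <- pad + b + 1; cx <- pad + a + 1
  m[((row(m) - cy) / b)^2 + ((col(m) - cx) / a)^2 <= 1] <- 1
  m
}

# analytic ellipse perimeter by numeric quadrature (independent oracle)
ellipse_perimeter <- function(a, b) {
  e2 <- 1 - (b / a)^2
  4 * a * integrate(function(t) sqrt(1 - e2 * sin(t)^2), 0, pi / 2,
                    rel.tol = 1e-10)$value
}

# binary stack of analytic spheres/ellipsoids on the reference voxel grid
shape_stack <- function(centers, semi_axes, field_um,
                        voxel_size = c(0.25, 0.1, 0.1), value = 1) {
  d <- as.integer(ceiling(field_um / voxel_size))
  zc <- (seq_len(d[1]) - 1) * voxel_size[1]
  yc <- (seq_len(d[2]) - 1) * voxel_size[2]
  xc <- (seq_len(d[3]) - 1) * voxel_size[3]
  arr <- array(0, d)
  for (i in seq_len(nrow(centers))) {
    ax <- semi_axes[i, ]
    m <- outer(outer(((zc - centers[i, 1]) / ax[1])^2,
                     ((yc - centers[i, 2]) / ax[2])^2, "+"),
               ((xc - centers[i, 3]) / ax[3])^2, "+") <= 1
    arr[m] <- value
  }
  voxel_grid(arr, voxel_size)
}

sphere_stack <- function(r, voxel_size = c(0.25, 0.1, 0.1), margin = 1.5) {
  ctr <- r + margin
  shape_stack(matrix(rep(ctr, 3), 1), matrix(rep(r, 3), 1),
              rep(2 * ctr, 3), voxel_size)
}

# synthetic constant-plus-noise image2d
flat_image <- function(value, n = 64, pixel_size = 1)
  image2d(matrix(value, n, n), pixel_size)
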