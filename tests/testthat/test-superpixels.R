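regions_are_4connected <- function(labels) {
  for (l in unique(as.vector(labels))) {
    m <- labels == l
    idx <- which(m, arr.ind = TRUE)
    # flood fill from the first member
    seen <- matrix(FALSE, nrow(labels), ncol(labels))
    stack <- list(idx[1, ])
    seen[idx[1, 1], idx[1, 2]] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= nrow(m) && q[2] >= 1 && q[2] <= ncol(m) &&
            m[q[1], q[2]] && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
    if (sum(seen) != sum(m)) return(FALSE)
  }
  TRUE
}

test_that("a constant 64x64 image splits into about 64 compact regions", {
  spx <- segment_superpixels(matrix(0.5, 64, 64), rSize = 8, reqStr = 0.01)
  expect_gte(spx$n, 32)
  expect_lte(spx$n, 128)
  expect_true(regions_are_4connected(spx$labels))
})

test_that("superpixel labels always partition the image", {
  ph <- generate_phantom(phantom_spec(height = 64, width = 64, seed = 2))
  spx <- segment_superpixels(ph$image)
  expect_equal(dim(spx$labels), dim(ph$image))
  expect_true(all(spx$labels >= 1 & spx$labels <= spx$n))
  expect_setequal(unique(as.vector(spx$labels)), seq_len(spx$n))
  # region count near (H W) / rSize^2 on textured-but-structured input
  expect_gte(spx$n, 64 * 64 / 64 / 2)
  expect_lte(spx$n, 64 * 64 / 64 * 2)
  expect_true(regions_are_4connected(spx$labels))
})

test_that("tiny images collapse to a single region and rSize is validated", {
  spx <- segment_superpixels(matrix(runif(30), 5, 6), rSize = 8)
  expect_equal(spx$n, 1L)
  expect_true(all(spx$labels == 1L))
  expect_error(segment_superpixels(matrix(0, 4, 4), rSize = 1))
})

test_that("superpixel centers lie inside their own region", {
  ph <- generate_phantom(phantom_spec(height = 64, width = 64, seed = 3))
  spx <- segment_superpixels(ph$image)
  ctr <- discrn:::superpixel_centers(spx)
  expect_equal(nrow(ctr), spx$n)
  expect_equal(spx$labels[ctr], seq_len(spx$n), ignore_attr = TRUE)
})
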