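test_that("switching function takes its closed-form values", {
  expect_identical(switching_function(0, 7), 1)
  expect_identical(switching_function(7, 7), 0.5)  # removable 0/0 at r = r0
  expect_equal(switching_function(14, 7), 1 / 65, tolerance = 1e-15)
})

test_that("switching function is strictly decreasing and bounded in (0, 1]", {
  set.seed(11)
  r <- sort(runif(500, 0, 40))
  s <- switching_function(r, 7)
  expect_true(all(diff(s) < 0))
  expect_true(all(s > 0 & s <= 1))
  expect_error(switching_function(1, r0 = 0), "positive")
  expect_error(switching_function(-1, 7), "non-negative")
})

test_that("structures round-trip through PDB with chain selection", {
  res <- data.frame(chain = rep(c("A", "B"), c(3, 2)),
                    resno = c(1:3, 1:2),
                    resid3 = c("ALA", "GLY", "TRP", "SER", "LYS"),
                    x = c(0, 3.8, 7.6, 20, 23.8), y = 0, z = 0,
                    stringsAsFactors = FALSE)
  path <- write_test_pdb(res)

  m <- read_structure(path)
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m$residues), 5)

  a <- read_structure(path, chain = "A")
  expect_equal(a$residues$position, 1:3)
  expect_equal(a$residues$aa, c("A", "G", "W"))
  expect_error(read_structure(path, chain = "C"), "available chains: A, B")
})

test_that("residues without a C-alpha are excluded with a warning", {
  res <- data.frame(chain = "A", resno = c(1, 2, 3),
                    resid3 = "ALA", x = c(0, 4, 8), y = 0, z = 0,
                    stringsAsFactors = FALSE)
  ## residue 5 contributes only a side-chain atom
  extra <- data.frame(chain = "A", resno = 5, resid3 = "ALA",
                      elety = "CB", elesy = "C", x = 12, y = 0, z = 0,
                      stringsAsFactors = FALSE)
  path <- write_test_pdb(res, extra_atoms = extra)
  expect_warning(m <- read_structure(path), "without a C-alpha")
  expect_equal(nrow(m$residues), 3)
  expect_false(5 %in% m$atoms$position)
})

test_that("renumbering remaps author numbering to 1..n with a mapping", {
  res <- data.frame(chain = "A", resno = c(10, 11, 15),
                    resid3 = "GLY", x = c(0, 4, 8), y = 0, z = 0,
                    stringsAsFactors = FALSE)
  path <- write_test_pdb(res)
  expect_message(m <- read_structure(path, renumber = TRUE), "renumbered")
  expect_equal(m$residues$position, 1:3)
  expect_equal(m$numbering$author, c(10, 11, 15))
})

test_that("weighted contact number matches pairwise closed forms", {
  m2 <- model_from_coords(rbind(c(0, 0, 0), c(7, 0, 0)))
  expect_equal(weighted_contact_number(m2)$wcn, c(0.5, 0.5))

  m3 <- model_from_coords(rbind(c(0, 0, 0), c(7, 0, 0), c(14, 0, 0)))
  w <- weighted_contact_number(m3)$wcn
  expect_equal(w[2], 1.0)                       # 0.5 + 0.5
  expect_equal(w[1], 0.5 + 1 / 65)
  expect_error(weighted_contact_number(model_from_coords(cbind(0, 0, 0))),
               "at least 2")
})

test_that("vectorized WCN equals the naive double loop", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(50:150, 1)
    xyz <- matrix(runif(3 * n, 0, 40), ncol = 3)
    w <- weighted_contact_number(model_from_coords(xyz))$wcn
    brute <- vapply(seq_len(n), function(i) {
      s <- 0
      for (j in seq_len(n)) {
        if (j != i) {
          r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
          s <- s + (1 - (r / 7)^6) / (1 - (r / 7)^12)
        }
      }
      s
    }, numeric(1))
    expect_equal(w, brute, tolerance = 1e-12)
  }
})

test_that("WCN is invariant under rigid motion and grows with added chains", {
  set.seed(31)
  n <- 80
  xyz <- matrix(runif(3 * n, 0, 30), ncol = 3)
  w0 <- weighted_contact_number(model_from_coords(xyz))$wcn

  ## random rotation (QR of a random matrix) plus translation
  qr_ <- qr(matrix(rnorm(9), 3))
  rot <- qr.Q(qr_) * sign(diag(qr.R(qr_)))
  moved <- xyz %*% rot + matrix(rep(c(5, -3, 12), each = n), ncol = 3)
  w1 <- weighted_contact_number(model_from_coords(moved))$wcn
  expect_equal(w0, w1, tolerance = 1e-9)

  ## oligomer context: adding a second chain only adds positive terms
  xyz2 <- xyz + matrix(rep(c(10, 0, 0), each = n), ncol = 3)
  olig <- funsites:::new_structure_model(rbind(
    data.frame(chain = "A", position = 1:n, aa = "A",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
    data.frame(chain = "B", position = 1:n, aa = "A",
               x = xyz2[, 1], y = xyz2[, 2], z = xyz2[, 3])))
  wo <- weighted_contact_number(olig)
  expect_true(all(wo$wcn[wo$chain == "A"] >= w0))
})

test_that("minimum distance to sites matches hand geometry and brute force", {
  m3 <- model_from_coords(rbind(c(0, 0, 0), c(7, 0, 0), c(14, 0, 0)))
  d <- min_distance_to_sites(m3, 1)
  expect_equal(d$distance, c(0, 7, 14))
  expect_equal(min_distance_to_sites(m3, 1:3)$distance, c(0, 0, 0))

  set.seed(41)
  xyz <- matrix(runif(90, 0, 25), ncol = 3)
  m <- model_from_coords(xyz)
  sites <- c(3, 17, 25)
  d <- min_distance_to_sites(m, sites)$distance
  brute <- vapply(1:30, function(i) {
    min(vapply(sites, function(s) sqrt(sum((xyz[i, ] - xyz[s, ])^2)),
               numeric(1)))
  }, numeric(1))
  expect_equal(d, brute, tolerance = 1e-9)

  expect_error(min_distance_to_sites(m, integer(0)), "non-empty")
  expect_error(min_distance_to_sites(m, 99), "not in model")
})

test_that("relative exposure flags buried residues and honours the threshold", {
  ## one isolated glycine: nothing occludes it
  iso <- funsites:::new_structure_model(
    data.frame(chain = "A", position = 1, aa = "G", x = 0, y = 0, z = 0),
    atoms = data.frame(chain = "A", position = 1, aa = "G",
                       elety = "CA", elesy = "C", x = 0, y = 0, z = 0))
  e <- relative_exposure(iso)
  expect_equal(e$rel_sasa, 1, tolerance = 0.01)
  expect_false(e$buried)

  ## a residue enclosed in a tight shell of neighbours is buried
  shell <- as.matrix(expand.grid(x = c(-3, 0, 3), y = c(-3, 0, 3),
                                 z = c(-3, 0, 3)))
  shell <- shell[rowSums(shell^2) > 0, ]
  atoms <- rbind(
    data.frame(chain = "A", position = 1, aa = "G", elety = "CA",
               elesy = "C", x = 0, y = 0, z = 0),
    data.frame(chain = "A", position = 1 + seq_len(nrow(shell)), aa = "G",
               elety = "CA", elesy = "C",
               x = shell[, 1], y = shell[, 2], z = shell[, 3]))
  dense <- funsites:::new_structure_model(
    data.frame(chain = "A", position = atoms$position, aa = "G",
               x = atoms$x, y = atoms$y, z = atoms$z),
    atoms = atoms)
  e <- relative_exposure(dense)
  expect_true(e$buried[e$position == 1])
  expect_lt(e$rel_sasa[e$position == 1], 0.2)

  ## threshold 0 can never flag anything buried
  e0 <- relative_exposure(dense, threshold = 0)
  expect_false(any(e0$buried))

  expect_error(relative_exposure(model_from_coords(cbind(0:1, 0, 0))),
               "keep_atoms")
})
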