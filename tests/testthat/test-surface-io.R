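test_that("icosphere has the expected subdivision counts and sphere topology", {
  s <- fx_sphere3()
  expect_equal(n_vertices(s), 642L)
  expect_equal(n_faces(s), 1280L)
  expect_equal(euler_characteristic(s), 2L)
  expect_true(is_closed_mesh(s))
  expect_true(is_oriented_mesh(s))
})

test_that("surfaces round-trip through every supported format", {
  mesh <- icosphere(7.3, 2)
  for (fmt in c("ply", "off", "freesurfer", "gifti")) {
    path <- tempfile(fileext = switch(fmt, ply = ".ply", off = ".off",
                                      gifti = ".surf.gii", ".srf"))
    write_surface(mesh, path, format = fmt)
    back <- read_surface(path, format = fmt)
    expect_identical(back$faces, mesh$faces)          # bit-exact connectivity
    tol <- if (fmt %in% c("freesurfer", "gifti")) 1e-5 else 1e-6
    expect_lt(max(abs(back$vertices - mesh$vertices)), tol)
    # auto-detection finds the format from magic bytes, not the extension
    hidden <- tempfile(fileext = ".dat")
    file.copy(path, hidden)
    expect_identical(read_surface(hidden, format = "auto")$faces, mesh$faces)
    unlink(c(path, hidden))
  }
})

test_that("unreadable and degenerate surface inputs are rejected", {
  expect_error(read_surface(tempfile()), "not found")
  junk <- tempfile()
  writeBin(as.raw(c(1, 2, 3, 4, 5, 6, 7, 8)), junk)
  expect_error(read_surface(junk), "magic")
  empty <- triangle_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3))
  expect_error(write_surface(empty, tempfile(fileext = ".ply")), "empty")
  expect_error(triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                             rbind(c(1L, 1L, 2L))), "degenerate")
  expect_error(triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                             rbind(c(1L, 2L, 4L))), "outside")
  # inconsistently oriented mesh: two faces traverse a shared edge identically
  bad <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 4",
               "property double x", "property double y", "property double z",
               "element face 2", "property list uchar int vertex_indices",
               "end_header",
               "0 0 0", "1 0 0", "0 1 0", "1 1 0",
               "3 0 1 2", "3 0 1 3"), bad)
  expect_error(read_surface(bad), "oriented")
})

test_that("vertex fields round-trip in curv and csv dialects and check alignment", {
  mesh <- fx_sphere3()
  field <- vertex_field(seq_len(642) / 100, mesh, units = "mm")
  for (fmt in c("curv", "csv")) {
    path <- tempfile()
    write_vertex_field(field, path, mesh, format = fmt)
    back <- read_vertex_field(path, mesh)
    tol <- if (fmt == "curv") 1e-6 else 1e-9      # curv stores float32
    expect_lt(max(abs(as.numeric(back) - as.numeric(field))), tol)
    unlink(path)
  }
  # constant field of ones round-trips exactly even through float32
  ones <- vertex_field(rep(1, 642), mesh)
  p <- tempfile()
  write_vertex_field(ones, p, mesh, format = "curv")
  expect_identical(as.numeric(read_vertex_field(p, mesh)), rep(1, 642))
  # length mismatch reports both counts
  short <- tempfile(fileext = ".csv")
  write.csv(data.frame(vertex = 0:640, value = 1), short, row.names = FALSE)
  expect_error(read_vertex_field(short, mesh), "641.*642")
})

test_that("csv vertex fields are parsed in 0-based index order", {
  mesh <- icosphere(1, 1)
  path <- tempfile(fileext = ".csv")
  n <- n_vertices(mesh)
  shuffled <- sample(n)
  write.csv(data.frame(vertex = shuffled - 1L, value = shuffled * 10),
            path, row.names = FALSE)
  back <- read_vertex_field(path, mesh)
  expect_equal(as.numeric(back), seq_len(n) * 10)
  expect_identical(readLines(path, n = 1L), "\"vertex\",\"value\"")
})
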