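test_that("PDB round-trip preserves atoms, labels and insertion codes", {
  cx <- toy_complex()
  f <- tempfile(fileext = ".pdb")
  write_structure(cx, f)
  cx2 <- read_structure(f, cx$annotation)
  expect_equal(nrow(cx2$atoms), nrow(cx$atoms))
  expect_identical(cx2$atoms$elety, cx$atoms$elety)
  expect_identical(res_label <- h3graft:::res_label(cx2$atoms$resno, cx2$atoms$insert),
                   h3graft:::res_label(cx$atoms$resno, cx$atoms$insert))
  expect_true(any(cx2$atoms$insert != ""))   # insertion codes survive
  expect_coords_equal(h3graft:::cx_coords(cx2), round(h3graft:::cx_coords(cx), 3))
  expect_equal(h3_length(cx2), 13L)
  # idempotence of read-write-read
  f2 <- tempfile(fileext = ".pdb")
  write_structure(cx2, f2)
  cx3 <- read_structure(f2, cx$annotation)
  expect_identical(cx3$atoms, cx2$atoms)
})

test_that("multi-model files contribute only the first model", {
  cx <- toy_complex()
  f1 <- tempfile(fileext = ".pdb"); f2 <- tempfile(fileext = ".pdb")
  write_structure(cx, f1)
  lines <- readLines(f1)
  atom <- grep("^ATOM", lines, value = TRUE)
  shifted <- sub("^(.{30})(........)", "\\1  99.000", atom[1])
  writeLines(c("MODEL        1", atom, "ENDMDL",
               "MODEL        2", shifted, atom[-1], "ENDMDL", "END"), f2)
  cx2 <- read_structure(f2, cx$annotation)
  expect_equal(nrow(cx2$atoms), nrow(cx$atoms))
  expect_equal(cx2$atoms$x[1], round(cx$atoms$x[1], 3))
  rep <- prepare_complex(cx2)$report
  expect_equal(rep$copies_removed, 1L)
})

test_that("invalid annotations are rejected with informative errors", {
  cx <- toy_complex()
  ann <- cx$annotation
  # H3 on two chains
  bad <- ann
  bad$region[bad$chain == "L" & bad$res_label == "5"] <- "H3"
  expect_error(abcomplex(cx$atoms, bad), "more than one chain")
  # annotated residue absent from coordinates
  bad2 <- rbind(ann, data.frame(chain = "H", res_label = "999",
                                region = "FR"))
  expect_error(abcomplex(cx$atoms, bad2), "999")
  # no H3 at all
  bad3 <- ann[ann$region != "H3", ]
  expect_error(abcomplex(cx$atoms, bad3), "no H3")
})

test_that("preparation removes solvent, finds disulfides, rebuilds side chains", {
  cx <- toy_complex()
  at <- cx$atoms
  hoh <- do.call(rbind, lapply(1:10, function(i)
    data.frame(chain = "W", resno = i, insert = "", resid = "HOH",
               elety = "O", elem = "O", x = 200 + i, y = 0, z = 0, o = 1,
               stringsAsFactors = FALSE)))
  na <- data.frame(chain = "W", resno = 11L, insert = "", resid = "NA",
                   elety = "NA", elem = "N", x = 300, y = 0, z = 0, o = 1,
                   stringsAsFactors = FALSE)
  cx2 <- abcomplex(rbind(at, hoh, na), cx$annotation)
  prep <- prepare_complex(cx2)
  expect_equal(prep$report$waters_ions_removed, 11L)
  expect_false(any(prep$complex$atoms$resid %in% c("HOH", "NA")))
  # idempotence
  prep2 <- prepare_complex(prep$complex)
  expect_identical(prep2$complex$atoms, prep$complex$atoms)
  expect_equal(prep2$report$waters_ions_removed, 0L)

  # two CYS with SG-SG ~2.03 A
  mkcys <- function(chain, resno, sgx) {
    data.frame(chain = chain, resno = resno, insert = "", resid = "CYS",
               elety = c("N", "CA", "C", "O", "CB", "SG"),
               elem = c("N", "C", "C", "O", "C", "S"),
               x = c(100, 101.4, 102, 102, 101.8, sgx),
               y = c(0, 0, 1.3, 2.5, -1.3, -1.3),
               z = c(0, 0, 0, 0, 1.1, 1.1), o = 1, stringsAsFactors = FALSE)
  }
  cys <- rbind(mkcys("X", 1L, 103.83), mkcys("X", 2L, 101.80))
  cys$x[7:12] <- cys$x[7:12] + 4     # separate backbones
  cys$x[12] <- cys$x[6] + 2.03       # but SGs 2.03 apart
  cx3 <- abcomplex(rbind(at, cys), cx$annotation)
  prep3 <- prepare_complex(cx3)
  expect_false(is.null(prep3$complex$disulfides))
  expect_equal(nrow(prep3$complex$disulfides), 1L)
  expect_equal(prep3$complex$disulfides$dist, 2.03, tolerance = 1e-6)

  # missing OG of a serine is rebuilt at ideal geometry
  ser_rows <- which(at$resid == "SER")
  stopifnot(length(ser_rows) > 0)
  og <- which(at$resid == "SER" & at$elety == "OG")[1]
  cx4 <- abcomplex(at[-og, ], cx$annotation)
  prep4 <- prepare_complex(cx4)
  expect_gte(prep4$report$missing_sidechains_completed, 1L)
  key <- h3graft:::atom_keys(cx)[og]
  rows <- which(h3graft:::atom_keys(prep4$complex) == key)
  a4 <- prep4$complex$atoms[rows, ]
  expect_true("OG" %in% a4$elety)
  cb <- as.numeric(a4[a4$elety == "CB", c("x", "y", "z")])
  ogx <- as.numeric(a4[a4$elety == "OG", c("x", "y", "z")])
  expect_equal(h3graft:::vnorm(ogx - cb), 1.428, tolerance = 0.02)
})

test_that("H3 index map follows the internal numbering convention", {
  expect_equal(h3_labels(10), c(as.character(93:100), "101", "102"))
  expect_equal(h3_labels(13),
               c(as.character(93:100), "100A", "100B", "100C", "101", "102"))
  expect_equal(h3_labels(7), c("93", "94", "95", "96", "97", "101", "102"))
  cx <- toy_complex()
  expect_equal(length(cx$h3_map), nchar(h3_sequence(cx)))
  expect_false(anyDuplicated(cx$h3_map) > 0)
  # flank residues exist with full backbone
  for (lab in c("90", "91", "92", "103", "104", "105")) {
    bb <- h3graft:::residue_backbone(cx, "H", lab)
    expect_false(any(vapply(bb, is.null, TRUE)))
  }
})

test_that("oversized names are refused on write", {
  cx <- toy_complex()
  cx$atoms$resid[1] <- "ABCD"
  expect_error(write_structure(cx, tempfile()), "field width")
})
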