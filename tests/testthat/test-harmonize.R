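test_that("palindromic classification follows the allele-pair definition", {
  expect_true(classify_palindromic("A", "T"))
  expect_true(classify_palindromic("T", "A"))
  expect_true(classify_palindromic("C", "G"))
  expect_false(classify_palindromic("A", "G"))
  expect_equal(classify_palindromic(c("A", "C", "A"), c("T", "G", "C")),
               c(TRUE, TRUE, FALSE))
})

test_that("swapped outcome alleles flip the outcome beta", {
  expo <- make_ss("rs1", p = 1e-9, beta = 0.10, ea = "A", oa = "G")
  outc <- make_ss("rs1", p = 0.01, beta = -0.05, ea = "G", oa = "A",
                  trait = "out")
  h <- harmonize(expo, outc)
  expect_equal(h$effect_allele, "A")
  expect_equal(unname(h$bx[1, 1]), 0.10)
  expect_equal(h$by, 0.05)
})

test_that("complementary-strand representations are mapped before aligning", {
  expo <- make_ss("rs1", p = 1e-9, beta = 0.10, ea = "A", oa = "G")
  outc <- make_ss("rs1", p = 0.01, beta = 0.07, ea = "T", oa = "C",
                  trait = "out")
  h <- harmonize(expo, outc)
  expect_equal(h$by, 0.07)
  # complementary swapped: T/C reported as C/T flips the sign
  outc2 <- make_ss("rs1", p = 0.01, beta = 0.07, ea = "C", oa = "T",
                   trait = "out")
  h2 <- harmonize(expo, outc2)
  expect_equal(h2$by, -0.07)
})

test_that("palindromic variants without frequencies are excluded", {
  expo <- make_ss(c("rs1", "rs2"), p = c(1e-9, 1e-9), beta = c(0.1, 0.1),
                  ea = c("A", "A"), oa = c("T", "G"))
  outc <- make_ss(c("rs1", "rs2"), p = c(0.01, 0.01), beta = c(0.05, 0.05),
                  ea = c("A", "A"), oa = c("T", "G"), trait = "out")
  h <- harmonize(expo, outc)
  expect_equal(h$variant_id, "rs2")
  expect_equal(h$exclusions$variant_id, "rs1")
  expect_equal(h$exclusions$reason, "palindromic")
})

test_that("frequency rescue orients palindromic variants when informative", {
  expo <- make_ss("rs1", p = 1e-9, beta = 0.1, ea = "A", oa = "T", eaf = 0.1)
  # same minor allele side: copy
  outc <- make_ss("rs1", p = 0.01, beta = 0.05, ea = "A", oa = "T",
                  eaf = 0.12, trait = "out")
  h <- harmonize(expo, outc, use_eaf = TRUE)
  expect_equal(h$by, 0.05)
  # frequencies on opposite sides of 0.5: the outcome is on the other strand
  outc2 <- make_ss("rs1", p = 0.01, beta = 0.05, ea = "A", oa = "T",
                   eaf = 0.88, trait = "out")
  h2 <- harmonize(expo, outc2, use_eaf = TRUE)
  expect_equal(h2$by, -0.05)
  # ambiguous frequency near 0.5 still excluded
  outc3 <- make_ss("rs1", p = 0.01, beta = 0.05, ea = "A", oa = "T",
                   eaf = 0.45, trait = "out")
  h3 <- harmonize(expo, outc3, use_eaf = TRUE)
  expect_equal(h3$exclusions$reason, "palindromic")
})

test_that("irreconcilable allele pairs are excluded as mismatches", {
  expo <- make_ss("rs1", p = 1e-9, beta = 0.1, ea = "A", oa = "G")
  outc <- make_ss("rs1", p = 0.01, beta = 0.05, ea = "A", oa = "C",
                  trait = "out")
  h <- harmonize(expo, outc)
  expect_equal(h$exclusions$reason, "allele_mismatch")
  expect_equal(n_snps(h), 0L)
})

test_that("zero shared variants is a data error", {
  expo <- make_ss("rs1", p = 1e-9)
  outc <- make_ss("rs2", p = 0.01, trait = "out")
  expect_error(harmonize(expo, outc), class = "mrlink_data_error")
})

test_that("harmonization output is invariant to the input representation", {
  # the fixture outcome mixes copied, swapped and strand-flipped records;
  # rebuilding it in the aligned representation must give identical rows
  fx <- fixture_bundle("asd_to_ea")
  inst <- clump(select_instruments(fx$exposure, fx$p_threshold), fx$ld)
  shared <- intersect(inst$variant_id, fx$outcome$variant_id)
  inst <- sumstats(as.data.frame(inst)[inst$variant_id %in% shared, ],
                   trait_id = trait_id(inst))
  h <- harmonize(inst, fx$outcome)
  expect_equal(n_snps(h), length(shared))
  # magnitudes are preserved: only signs and labels may change
  out_df <- as.data.frame(fx$outcome)
  m <- match(h$variant_id, out_df$variant_id)
  expect_equal(abs(h$by), abs(out_df$beta[m]))
  expect_equal(h$sy, out_df$se[m])
  # already-aligned input harmonizes to itself (involution safety)
  aligned_out <- sumstats(data.frame(
    variant_id = h$variant_id, chromosome = out_df$chromosome[m],
    position = out_df$position[m], effect_allele = h$effect_allele,
    other_allele = h$other_allele, eaf = NA_real_, beta = h$by,
    se = h$sy, pvalue = out_df$pvalue[m], n = NA_real_,
    stringsAsFactors = FALSE), trait_id = "out2")
  h2 <- harmonize(inst, aligned_out)
  expect_equal(h2$by, h$by)
  expect_equal(h2$bx, h$bx)
})

test_that("shared variants partition exactly into rows and exclusions", {
  set.seed(5)
  sim <- simulate_pair(sim_config(n_snps = 40, theta = 0.2,
                                  palindromic_fraction = 0.25, seed = 31))
  h <- harmonize(sim$exposure, sim$outcome)
  expect_setequal(c(h$variant_id, h$exclusions$variant_id),
                  sim$exposure$variant_id)
  expect_length(intersect(h$variant_id, h$exclusions$variant_id), 0)
  # every palindromic variant is excluded with the right reason
  expect_setequal(h$exclusions$variant_id, sim$truth$palindromic)
  expect_true(all(h$exclusions$reason == "palindromic"))
})

test_that("multivariable harmonization aligns both exposures to the first", {
  e1 <- make_ss("rs1", p = 1e-9, beta = 0.1, ea = "A", oa = "G")
  e2 <- make_ss("rs1", p = 1e-9, beta = -0.2, ea = "G", oa = "A",
                trait = "expo2")
  outc <- make_ss("rs1", p = 0.01, beta = 0.05, ea = "T", oa = "C",
                  trait = "out")
  h <- harmonize(list(e1, e2), outc)
  expect_equal(dim(h$bx), c(1L, 2L))
  expect_equal(h$bx[1, ], c(trait = 0.1, expo2 = 0.2),
               ignore_attr = TRUE)
  expect_equal(h$by, 0.05)
})
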