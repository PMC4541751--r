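test_that("pair enumeration covers the vaccine x symptom cross product, once per report", {
  a <- countPairs(makeFixture("tiny3"))
  rec <- associationRecords(a)
  expect_identical(nrow(rec), 4L)
  expect_setequal(paste(rec$vaccine, rec$symptom),
                  c("DTAP Fever", "MMR Fever", "FLU Rash", "FLU Fever"))
  expect_true(all(rec$nTotal == 1L))

  # a vaccine listed twice in a report still contributes one count
  dup <- ReportSet("D1", 2000L, "F", 5,
                   vaccines = list(c("DTAP", "DTAP")),
                   symptoms = list("Fever"))
  rec2 <- associationRecords(countPairs(dup))
  expect_identical(rec2$nTotal, 1L)

  expect_error(countPairs(ReportSet(character(0), integer(0), character(0),
                                    numeric(0), list(), list())),
               "empty")
})

test_that("the reporting ratio follows its closed form with guarded denominators", {
  # (4/10)/(20/100) = 2
  expect_identical(prr(4, 10, 20, 100), 2)
  a <- computePrr(countPairs(makeFixture("toy_prr")))
  rec <- associationRecords(a)
  expect_identical(rec$prrOverall[rec$vaccine == "V" & rec$symptom == "S"], 2)

  # a vaccine present in every report forces a = c and b = d, hence exactly 1
  uni <- ReportSet(sprintf("U%02d", 1:20), rep(2000L, 20),
                   rep(c("F", "M"), 10), rep(30, 20),
                   vaccines = rep(list("UNI"), 20),
                   symptoms = c(rep(list("S1"), 7), rep(list("S2"), 13)))
  recU <- associationRecords(computePrr(countPairs(uni)))
  expect_true(all(recU$prrOverall == 1))

  # zero denominators are flagged undefined, never 0 or Inf
  expect_true(is.na(prr(0, 0, 5, 10)))
  expect_true(is.na(prr(0, 5, 0, 10)))
  expect_true(is.na(prr(0, 0, 0, 0)))
  expect_identical(prr(c(4, 0), c(10, 0), c(20, 3), c(100, 10)),
                   c(2, NA))
})

test_that("sex strata with no symptom occurrences yield flagged-undefined ratios", {
  # symptom only ever reported by female patients; male stratum has c = 0
  rs <- ReportSet(sprintf("Z%02d", 1:6), rep(2010L, 6),
                  c("F", "F", "F", "M", "M", "M"), rep(20, 6),
                  vaccines = rep(list("VX"), 6),
                  symptoms = c(rep(list("OnlyF"), 3), rep(list("Other"), 3)))
  rec <- associationRecords(computePrr(countPairs(rs)))
  row <- rec[rec$symptom == "OnlyF", ]
  expect_true(is.na(row$prrM))
  expect_identical(row$prrF, 1)  # VX in every report of the stratum
})

test_that("significance filtering is strictly greater-than and drops undefined values", {
  rs <- makeFixture("toy_prr")
  a <- computePrr(countPairs(rs))
  sig <- significantAssociations(a, "overall")
  expect_true(all(sig$prr > 1))
  expect_true("V" %in% sig$vaccine)

  fake <- methods::initialize(a, records = data.frame(
    vaccine = c("A", "B", "C", "D"), symptom = rep("S", 4),
    nTotal = 1:4, nF = 0L, nM = 0L,
    prrOverall = c(0.5, 1.0, 1.0001, NA),
    prrF = NA_real_, prrM = NA_real_, stringsAsFactors = FALSE),
    yearly = data.frame(vaccine = character(0), symptom = character(0),
                        year = integer(0), n = integer(0),
                        prr = numeric(0)))
  kept <- significantAssociations(fake, "overall")
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$vaccine, "C")
  expect_error(significantAssociations(fake, "overall", threshold = 0),
               "positive")
})

test_that("yearly numerators sum to overall numerators when all years parse", {
  set.seed(401)
  rs <- randomReportSet(150)
  df <- reportTable(rs)
  df <- df[!is.na(df$year), ]
  rs2 <- ReportSet(df$report_id, df$year, df$sex, df$age, df$vaccines,
                   df$symptoms)
  a <- countPairs(rs2)
  rec <- associationRecords(a)
  yr <- yearlyRecords(a)
  ySum <- tapply(yr$n, paste(yr$vaccine, yr$symptom), sum)
  expect_equal(as.integer(ySum[paste(rec$vaccine, rec$symptom)]),
               rec$nTotal, ignore_attr = TRUE)
  # sex-split counts of F and M plus U reports cover the total
  expect_true(all(rec$nF + rec$nM <= rec$nTotal))
})

test_that("PRR is invariant under k-fold replication of every report", {
  rs <- makeFixture("toy_prr")
  df <- reportTable(rs)
  k <- 3L
  rep3 <- ReportSet(
    report_id = paste0(rep(df$report_id, k), "_", rep(seq_len(k),
                                                      each = nrow(df))),
    year = rep(df$year, k), sex = rep(df$sex, k), age = rep(df$age, k),
    vaccines = rep(df$vaccines, k), symptoms = rep(df$symptoms, k))
  r1 <- associationRecords(computePrr(countPairs(rs)))
  r3 <- associationRecords(computePrr(countPairs(rep3)))
  m <- merge(r1, r3, by = c("vaccine", "symptom"))
  expect_equal(m$prrOverall.x, m$prrOverall.y, tolerance = 1e-12)
  expect_identical(m$nTotal.y, m$nTotal.x * k)
})

test_that("formula-based PRRs agree exactly with exhaustive report scanning", {
  for (seed in c(11, 12, 13)) {
    set.seed(seed)
    rs <- randomReportSet(n = 120)
    a <- computePrr(countPairs(rs))
    rec <- associationRecords(a)
    pick <- rec[sample.int(nrow(rec), min(12, nrow(rec))), ]
    for (i in seq_len(nrow(pick))) {
      for (st in list("overall", "F", "M", 2001L)) {
        got <- if (identical(st, "overall")) pick$prrOverall[i]
          else if (identical(st, "F")) pick$prrF[i]
          else if (identical(st, "M")) pick$prrM[i]
          else {
            yr <- yearlyRecords(a)
            hit <- yr$vaccine == pick$vaccine[i] &
                   yr$symptom == pick$symptom[i] & yr$year == st
            if (any(hit)) yr$prr[hit] else NA_real_
          }
        want <- oraclePrr(rs, pick$vaccine[i], pick$symptom[i], st)
        if (identical(st, 2001L) && is.na(got)) {
          # pair absent from that year: oracle sees a = 0 (or undefined)
          expect_true(is.na(want) || want == 0)
        } else {
          expect_identical(got, want)
        }
      }
    }
  }
})

test_that("demographic distributions count the pair's reports by sex, age and year", {
  rs <- makeFixture("tiny3")
  d <- demographicDistribution(rs, "FLU", "Fever")
  expect_identical(d@nTotal, 1L)
  expect_identical(unname(d@sexCounts), c(1L, 0L, 0L))      # F, M, U
  expect_identical(unname(d@ageCounts["18-64"]), 1L)        # age 30
  expect_identical(d@byYearSex$n, 1L)
  expect_identical(d@byYearSex$year, 1991L)

  absent <- demographicDistribution(rs, "FLU", "Nothing")
  expect_identical(absent@nTotal, 0L)
  expect_true(all(absent@sexCounts == 0L))

  # partition property on a generated corpus: sexes and age groups each sum
  # to the pair total reported by countPairs
  set.seed(77)
  rr <- randomReportSet(200)
  rec <- associationRecords(countPairs(rr))
  top <- rec[which.max(rec$nTotal), ]
  dd <- demographicDistribution(rr, top$vaccine, top$symptom)
  expect_identical(dd@nTotal, top$nTotal)
  expect_identical(sum(dd@sexCounts), top$nTotal)
  expect_identical(sum(dd@ageCounts), top$nTotal)
})

test_that("association tables are written as TSV twins of the record set", {
  a <- computePrr(countPairs(makeFixture("tiny3")))
  f <- withr::local_tempfile(fileext = ".tsv")
  paths <- writeAssociationTable(a, f)
  tab <- read.delim(paths[1])
  expect_identical(nrow(tab), nrow(associationRecords(a)))
  ytab <- read.delim(paths[2])
  expect_identical(nrow(ytab), nrow(yearlyRecords(a)))
})
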