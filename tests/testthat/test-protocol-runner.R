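poolPath <- function() system.file("extdata", "protocols",
                                   "default_pool.json", package = "focalsim")

test_that("protocol pools load, select, and reject bad input", {
  pool <- loadProtocolPool(poolPath())
  expect_length(pool, 2)
  expect_equal(pool[[1]]@name, "Group 1")
  expect_equal(pool[[1]]@scenes$id[1], "00 MainMenu")
  expect_equal(pool[[1]]@scenes$param[4], "TLX")
  # parameter "0" means no extra configuration
  expect_equal(pool[[1]]@scenes$param[1], "0")
  # seeded random selection is reproducible
  s1 <- selectProtocol(pool, seed = 5)
  s2 <- selectProtocol(pool, seed = 5)
  expect_equal(s1@name, s2@name)
  expect_equal(selectProtocol(pool, "Group 2")@name, "Group 2")
  expect_error(selectProtocol(pool, "Group 9"), "no protocol")
  # empty / malformed pools
  empty <- tempfile(fileext = ".json")
  writeLines('{"protocols": []}', empty)
  expect_error(loadProtocolPool(empty), "empty")
  dup <- tempfile(fileext = ".json")
  writeLines(paste0('{"protocols": [',
    '{"name": "A", "scenes": [{"id": "x", "param": "0"}]},',
    '{"name": "A", "scenes": [{"id": "y", "param": "0"}]}]}'), dup)
  expect_error(loadProtocolPool(dup), "duplicate")
})

test_that("subject folders increment on collision and never overwrite", {
  root <- tempfile()
  p1 <- createSubjectFolder(root, "sub01")
  expect_equal(basename(p1), "sub01")
  marker <- file.path(p1, "keep.txt"); writeLines("x", marker)
  p2 <- createSubjectFolder(root, "sub01")
  expect_equal(basename(p2), "sub01_1")
  p3 <- createSubjectFolder(root, "sub01")
  expect_equal(basename(p3), "sub01_2")
  expect_true(file.exists(marker))  # earlier data untouched
})

test_that("protocols execute scenes in order into per-scene subfolders", {
  root <- tempfile()
  sub <- createSubjectFolder(root, "s1")
  ran <- character()
  registry <- list(
    menu = function(param, out_dir, ctx) {
      ran <<- c(ran, paste0("menu:", param))
      writeLines("m", file.path(out_dir, "m.txt"))
    },
    task = function(param, out_dir, ctx) {
      ran <<- c(ran, paste0("task:", param))
      writeLines("t", focalsim:::timestampedPath(out_dir, "resp"))
    })
  proto <- new("Protocol", name = "P",
               scenes = data.frame(id = c("menu", "task", "task"),
                                   param = c("0", "1", "2"),
                                   stringsAsFactors = FALSE))
  log <- runProtocol(proto, sub, registry)
  expect_equal(ran, c("menu:0", "task:1", "task:2"))
  expect_equal(log$status, rep("completed", 3))
  # one subfolder per protocol position (repeated scene ids get their own)
  expect_setequal(basename(list.dirs(sub, recursive = FALSE)),
                  c("01_menu", "02_task", "03_task"))
  # unknown scene id aborts with context
  bad <- new("Protocol", name = "B",
             scenes = data.frame(id = "nope", param = "0",
                                 stringsAsFactors = FALSE))
  expect_error(runProtocol(bad, sub, registry), "unknown scene")
})

test_that("repeat reruns a scene into the same subfolder; skip skips", {
  root <- tempfile()
  sub <- createSubjectFolder(root, "s2")
  registry <- list(
    a = function(param, out_dir, ctx)
      writeLines("x", focalsim:::timestampedPath(out_dir, "data")),
    b = function(param, out_dir, ctx)
      writeLines("y", focalsim:::timestampedPath(out_dir, "data")))
  proto <- new("Protocol", name = "P",
               scenes = data.frame(id = c("a", "b"), param = c("0", "0"),
                                   stringsAsFactors = FALSE))
  log <- runProtocol(proto, sub, registry, controls = c("run", "repeat"))
  expect_equal(log$status, c("completed", "repeated"))
  expect_length(list.files(file.path(sub, "02_b")), 2)  # two file sets
  # skip: scene 1 marked skipped, scene 2 runs
  sub2 <- createSubjectFolder(root, "s3")
  log2 <- runProtocol(proto, sub2, registry, controls = c("skip", "run"))
  expect_equal(log2$status, c("skipped", "completed"))
  expect_false(dir.exists(file.path(sub2, "01_a")))
  expect_length(list.files(file.path(sub2, "02_b")), 1)
})

test_that("questionnaires load by abbreviation and answers round-trip", {
  q <- loadQuestionnaire("TLX")
  expect_equal(q@abbreviation, "TLX")
  expect_equal(nrow(q@items), 6)
  expect_equal(q@items$id[1], "mental_demand")  # file order preserved
  expect_error(loadQuestionnaire("NOPE"), "no questionnaire")
  td <- tempfile()
  ans <- setNames(c(10, 20, 30, 40, 50, 60), q@items$id)
  p <- recordAnswers(q, ans, td)
  expect_match(basename(p), "^answers_\\d{8}T\\d{6}")
  back <- readAnswers(p)
  expect_equal(back[names(ans)], ans)
  expect_error(recordAnswers(q, c(bogus_item = 5), td), "unknown item")
})

test_that("a full default run writes the complete file taxonomy", {
  root <- tempfile()
  pool <- loadProtocolPool(poolPath())
  proto <- selectProtocol(pool, "Group 1")
  sub <- createSubjectFolder(root, "sub01")
  runProtocol(proto, sub, defaultSceneRegistry(),
              context = list(subject = "sub01", n_trials = 2))
  dirs <- basename(list.dirs(sub, recursive = FALSE))
  expect_setequal(dirs, c("01_00_MainMenu", "02_01_Baseline",
                          "03_02_Experiment", "04_03_Questionnaire"))
  exp_files <- list.files(file.path(sub, "03_02_Experiment"))
  expect_true(any(grepl("^gaze_", exp_files)))
  expect_true(any(grepl("^tuning_", exp_files)))
  expect_true(any(grepl("^responses_", exp_files)))
  q_files <- list.files(file.path(sub, "04_03_Questionnaire"))
  expect_true(any(grepl("^answers_", q_files)))
})
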