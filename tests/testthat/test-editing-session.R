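session_fixture <- function(seed = 20) {
  generate_chromatogram(fixture_spec(
    n_scans = 40L, peaks = list(peak_spec(20000, 5000, 2e4,
                                          random_pattern(4L, seed))),
    baseline_offset = 100, noise_sigma = 25, seed = seed))$chromatogram
}

# the pool of operations used by the random-walk tests
op_pool <- list(list("mean-normalize", list(target = 800)),
                list("savitzky-golay", list(window = 7L)),
                list("remove-background", list()),
                list("mean-normalize", list(target = 1200)))

replay <- function(x, ops) {
  for (op in ops)
    x <- apply_filter(chromatogram_selection(x), op[[1]], op[[2]])
  x
}

test_that("apply then undo restores the model exactly", {
  x <- session_fixture()
  s <- edit_session(x)
  apply_edit(s, "mean-normalize", list(target = 777))
  expect_false(identical(s$chromatogram, x))
  undo(s)
  expect_identical(s$chromatogram, x)
})

test_that("undo/redo follow the command-stack contract", {
  x <- session_fixture()
  s <- edit_session(x)
  apply_edit(s, "mean-normalize", list(target = 800))
  apply_edit(s, "savitzky-golay", list(window = 7L))
  after_ab <- s$chromatogram
  undo(s)
  expect_true(can_redo(s))
  redo(s)
  expect_identical(s$chromatogram, after_ab)  # undo+redo = apply A, apply B

  # a new apply clears the redo stack
  undo(s)
  apply_edit(s, "remove-background")
  expect_false(can_redo(s))
  expect_error(redo(s), "nothing to redo")
})

test_that("n applies followed by n undos restore the original", {
  x <- session_fixture(seed = 21)
  ns <- chromkit:::with_seed(30, sample(1:10, 3))
  for (n in ns) {
    s <- edit_session(x)
    picks <- chromkit:::with_seed(40 + n, sample(length(op_pool), n,
                                                 replace = TRUE))
    for (k in picks) apply_edit(s, op_pool[[k]][[1]], op_pool[[k]][[2]])
    for (i in seq_len(n)) undo(s)
    expect_identical(s$chromatogram, x)
    expect_false(can_undo(s))
  }
})

test_that("random apply/undo/redo walks equal the net-sequence replay", {
  x <- session_fixture(seed = 22)
  for (walk_seed in 1:5) {
    s <- edit_session(x)
    net <- list()          # shadow of the operations currently in effect
    undone <- list()
    moves <- chromkit:::with_seed(walk_seed, sample(c("apply", "undo", "redo"),
                                                    10, replace = TRUE,
                                                    prob = c(.5, .25, .25)))
    k <- 0L
    for (m in moves) {
      if (m == "apply") {
        k <- chromkit:::with_seed(walk_seed * 100L + k + 1L,
                                  sample(length(op_pool), 1))
        op <- op_pool[[k]]
        apply_edit(s, op[[1]], op[[2]])
        net <- c(net, list(op)); undone <- list()
      } else if (m == "undo" && can_undo(s)) {
        undo(s)
        undone <- c(undone, net[length(net)]); net <- net[-length(net)]
      } else if (m == "redo" && can_redo(s)) {
        redo(s)
        net <- c(net, undone[length(undone)]); undone <- undone[-length(undone)]
      }
    }
    expect_identical(s$chromatogram, replay(x, net))
  }
})

test_that("disabled reversibility keeps the stacks empty", {
  s <- edit_session(session_fixture(), reversibility = FALSE)
  apply_edit(s, "mean-normalize", list(target = 500))
  expect_false(can_undo(s))
  expect_length(s$undo_stack, 0L)
  expect_error(undo(s), "nothing to undo")
})

test_that("a failing operation mutates neither model nor stacks", {
  x <- session_fixture()
  s <- edit_session(x)
  apply_edit(s, "mean-normalize", list(target = 900))
  before <- s$chromatogram
  depth <- length(s$undo_stack)
  # window larger than the selection -> the filter itself fails
  expect_error(apply_edit(s, "savitzky-golay", list(window = 99L)))
  expect_error(apply_edit(s, "no-such-filter"))
  expect_identical(s$chromatogram, before)
  expect_length(s$undo_stack, depth)
  expect_false(can_redo(s))
})

test_that("exceeding the undo limit drops the oldest snapshot", {
  s <- edit_session(session_fixture(), undo_limit = 2)
  for (t in c(500, 600, 700)) apply_edit(s, "mean-normalize",
                                         list(target = t))
  expect_length(s$undo_stack, 2L)
  undo(s); undo(s)
  expect_error(undo(s), "nothing to undo")
  # the deepest reachable state is the one after the first (dropped) edit
  expect_equal(mean(tic_trace(session_selection(s))$abundance), 500,
               tolerance = 1e-9)
})

test_that("selection observers fire in order and can deregister", {
  s <- edit_session(session_fixture())
  log <- character()
  id1 <- on_selection_changed(s, function(sel) log <<- c(log, "first"))
  id2 <- on_selection_changed(s, function(sel) log <<- c(log, "second"))
  rts <- scan_times(s$chromatogram)
  set_selection(s, rts[5], rts[30])
  expect_identical(log, c("first", "second"))  # one event, both observers

  log <- character()
  apply_edit(s, "mean-normalize", list(target = 1000))
  undo(s)
  redo(s)
  expect_identical(log, rep(c("first", "second"), 3))

  remove_observer(s, id1)
  log <- character()
  set_selection(s)
  expect_identical(log, "second")
  remove_observer(s, id2)

  # callbacks receive the live selection
  seen <- NULL
  on_selection_changed(s, function(sel) seen <<- sel)
  set_selection(s, rts[2], rts[10])
  expect_s3_class(seen, "chromatogram_selection")
  expect_equal(length(selection_indices(seen)), 9L)
})

test_that("edits honour the session's selection window", {
  x <- session_fixture(seed = 23)
  s <- edit_session(x)
  rts <- scan_times(x)
  set_selection(s, rts[11], rts[30])
  apply_edit(s, "mean-normalize", list(target = 2000))
  expect_scans_identical(s$chromatogram, x, c(1:10, 31:40))
  inside <- tic_trace(chromatogram_selection(s$chromatogram, rts[11],
                                             rts[30]))
  expect_equal(mean(inside$abundance), 2000, tolerance = 1e-9)
})
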