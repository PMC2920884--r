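# Reversible editing sessions. A session owns a working copy of a
# chromatogram plus the active selection window; operations are applied
# through the filter registry and recorded as deep snapshots on an undo
# stack, so apply -> undo restores the model exactly. Snapshots were chosen
# over algebraic inverses because smoothing-type filters are not invertible;
# the cost is memory, accepted because the chromatogram is held fully in RAM.
# Reversibility can be disabled, in which case the stacks stay empty.

#' Open an editing session on a chromatogram
#'
#' @param chromatogram a `chromatogram`.
#' @param reversibility enable undo/redo snapshots (default `TRUE`).
#' @param undo_limit maximum undo depth; exceeding it silently drops the
#'   oldest snapshot (default `Inf`).
#' @return an environment of class `edit_session`.
#' @export
edit_session <- function(chromatogram, reversibility = TRUE,
                         undo_limit = Inf) {
  stopifnot(inherits(chromatogram, "chromatogram"))
  s <- new.env(parent = emptyenv())
  s$chromatogram <- chromatogram
  s$start_rt <- NULL; s$stop_rt <- NULL
  s$included_ions <- NULL; s$excluded_ions <- NULL
  s$reversibility <- isTRUE(reversibility)
  s$undo_limit <- undo_limit
  s$undo_stack <- list()
  s$redo_stack <- list()
  s$observers <- list()
  s$next_observer_id <- 1L
  class(s) <- "edit_session"
  s
}

#' @export
print.edit_session <- function(x, ...) {
  cat(sprintf("<edit_session: %d scans, undo %d, redo %d%s>\n",
              n_scans(x$chromatogram), length(x$undo_stack),
              length(x$redo_stack),
              if (x$reversibility) "" else ", reversibility off"))
  invisible(x)
}

#' Current selection of a session
#' @param session an `edit_session`.
#' @return a [chromatogram_selection()] for the session's window and filters.
#' @export
session_selection <- function(session) {
  stopifnot(inherits(session, "edit_session"))
  chromatogram_selection(session$chromatogram, session$start_rt,
                         session$stop_rt, session$included_ions,
                         session$excluded_ions)
}

#' Change the session's selection window
#'
#' Observers registered with [on_selection_changed()] are notified.
#'
#' @param session an `edit_session`.
#' @param start_rt,stop_rt window bounds in ms (`NULL` = full range).
#' @param included_ions,excluded_ions optional ion filter sets.
#' @return the session, invisibly.
#' @export
set_selection <- function(session, start_rt = NULL, stop_rt = NULL,
                          included_ions = NULL, excluded_ions = NULL) {
  stopifnot(inherits(session, "edit_session"))
  # validate before mutating
  chromatogram_selection(session$chromatogram, start_rt, stop_rt,
                         included_ions, excluded_ions)
  session$start_rt <- start_rt
  session$stop_rt <- stop_rt
  session$included_ions <- included_ions
  session$excluded_ions <- excluded_ions
  notify_observers(session)
  invisible(session)
}

notify_observers <- function(session) {
  sel <- session_selection(session)
  for (cb in session$observers) cb(sel)
  invisible(NULL)
}

#' Register a selection-change observer
#'
#' The callback is invoked with the new selection after every selection
#' mutation and after every apply/undo/redo, in registration order.
#'
#' @param session an `edit_session`.
#' @param callback function of one argument (the current selection).
#' @return an opaque registration id usable with [remove_observer()].
#' @export
on_selection_changed <- function(session, callback) {
  stopifnot(inherits(session, "edit_session"), is.function(callback))
  id <- sprintf("obs%d", session$next_observer_id)
  session$next_observer_id <- session$next_observer_id + 1L
  session$observers[[id]] <- callback
  id
}

#' Deregister a selection-change observer
#' @param session an `edit_session`.
#' @param id registration id returned by [on_selection_changed()].
#' @return the session, invisibly.
#' @export
remove_observer <- function(session, id) {
  session$observers[[id]] <- NULL
  invisible(session)
}

#' Apply a registered filter to the session (undoably)
#'
#' The filter runs on the session's current selection.  On success the result
#' replaces the session's chromatogram; with reversibility enabled a snapshot
#' of the previous state is pushed on the undo stack and the redo stack is
#' cleared.  A failing operation leaves model and stacks untouched
#' (atomicity), because the filter works on a copy.
#'
#' @param session an `edit_session`.
#' @param filter_id id of a registered filter.
#' @param params named list of filter parameters.
#' @param label optional human-readable command label.
#' @return the session, invisibly.
#' @export
apply_edit <- function(session, filter_id, params = list(),
                       label = filter_id) {
  stopifnot(inherits(session, "edit_session"))
  sel <- session_selection(session)
  result <- apply_filter(sel, filter_id, params)  # may stop(); nothing mutated
  if (session$reversibility) {
    cmd <- list(label = label, filter_id = filter_id, params = params,
                before = session$chromatogram)
    session$undo_stack <- c(session$undo_stack, list(cmd))
    if (length(session$undo_stack) > session$undo_limit)
      session$undo_stack <- session$undo_stack[-1L]
    session$redo_stack <- list()
  }
  session$chromatogram <- result
  notify_observers(session)
  invisible(session)
}

#' Undo the most recent edit
#'
#' @param session an `edit_session`.
#' @return the session, invisibly.
#' @export
undo <- function(session) {
  stopifnot(inherits(session, "edit_session"))
  k <- length(session$undo_stack)
  if (!k) stop("nothing to undo")
  cmd <- session$undo_stack[[k]]
  session$undo_stack <- session$undo_stack[-k]
  redo_cmd <- cmd
  redo_cmd$before <- session$chromatogram
  session$redo_stack <- c(session$redo_stack, list(redo_cmd))
  session$chromatogram <- cmd$before
  notify_observers(session)
  invisible(session)
}

#' Redo the most recently undone edit
#'
#' @param session an `edit_session`.
#' @return the session, invisibly.
#' @export
redo <- function(session) {
  stopifnot(inherits(session, "edit_session"))
  k <- length(session$redo_stack)
  if (!k) stop("nothing to redo")
  cmd <- session$redo_stack[[k]]
  session$redo_stack <- session$redo_stack[-k]
  undo_cmd <- cmd
  undo_cmd$before <- session$chromatogram
  session$undo_stack <- c(session$undo_stack, list(undo_cmd))
  session$chromatogram <- cmd$before
  notify_observers(session)
  invisible(session)
}

#' Can the session undo / redo?
#' @param session an `edit_session`.
#' @return logical.
#' @export
can_undo <- function(session) length(session$undo_stack) > 0L

#' @rdname can_undo
#' @export
can_redo <- function(session) length(session$redo_stack) > 0L
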