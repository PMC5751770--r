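# Object sinks: the destination the archive writer streams compressed
# blocks to as soon as each is ready. put() is durable and idempotent per
# name (re-putting the same object is a no-op, so a failed attempt can be
# retried); finalize() makes the archive readable. A sink can be a single
# local file, a directory of objects (one file per block, the layout a
# remote object store would mirror), or an in-memory store for tests.

#' Object sinks for archive output
#'
#' `sink_file()` concatenates objects into a single archive file with a
#' trailer index. `sink_dir()` stores one object per file under a
#' directory. `sink_memory()` keeps objects in memory. All honour the same
#' contract: `put(name, data)` (idempotent per name) followed by
#' `finalize()`.
#'
#' @param path Output file (for `sink_file`) or directory (for `sink_dir`).
#' @return An environment of class `fq_sink`.
#' @export
sink_file <- function(path) {
  s <- new.env(parent = emptyenv())
  s$kind <- "file"
  s$path <- path
  s$con <- file(path, "wb")
  s$offset <- 0
  s$toc <- list()
  s$put <- function(name, data) {
    if (!is.null(s$toc[[name]])) {
      if (s$toc[[name]]$length != length(data)) {
        fq_sink_error(sprintf("object '%s' re-put with different content", name),
                      object = name)
      }
      return(invisible(s$toc[[name]]$offset))
    }
    writeBin(data, s$con)
    s$toc[[name]] <- list(offset = s$offset, length = length(data))
    off <- s$offset
    s$offset <- s$offset + length(data)
    invisible(off)
  }
  s$object_offset <- function(name) s$toc[[name]]$offset
  s$finalize <- function() {
    if (!is.null(s$con)) {
      close(s$con)
      s$con <- NULL
    }
    invisible(TRUE)
  }
  s$discard <- function() {
    if (!is.null(s$con)) close(s$con)
    s$con <- NULL
    unlink(s$path)
  }
  class(s) <- "fq_sink"
  s
}

#' @rdname sink_file
#' @export
sink_dir <- function(path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  s <- new.env(parent = emptyenv())
  s$kind <- "dir"
  s$path <- path
  s$put <- function(name, data) {
    f <- file.path(path, name)
    if (file.exists(f)) {
      if (file.size(f) != length(data)) {
        fq_sink_error(sprintf("object '%s' re-put with different content", name),
                      object = name)
      }
      return(invisible(NA_real_))
    }
    writeBin(data, f)
    invisible(NA_real_)
  }
  s$get <- function(name) {
    f <- file.path(path, name)
    if (!file.exists(f)) fq_corruption_error(sprintf("missing object '%s'", name))
    readBin(f, "raw", n = file.size(f))
  }
  s$object_offset <- function(name) NA_real_
  s$finalize <- function() invisible(TRUE)
  s$discard <- function() unlink(path, recursive = TRUE)
  class(s) <- "fq_sink"
  s
}

#' @rdname sink_file
#' @export
sink_memory <- function() {
  s <- new.env(parent = emptyenv())
  s$kind <- "memory"
  s$objects <- list()
  s$put <- function(name, data) {
    if (!is.null(s$objects[[name]])) {
      if (!identical(s$objects[[name]], data)) {
        fq_sink_error(sprintf("object '%s' re-put with different content", name),
                      object = name)
      }
      return(invisible(NA_real_))
    }
    s$objects[[name]] <- data
    invisible(NA_real_)
  }
  s$get <- function(name) {
    if (is.null(s$objects[[name]])) {
      fq_corruption_error(sprintf("missing object '%s'", name))
    }
    s$objects[[name]]
  }
  s$object_offset <- function(name) NA_real_
  s$finalize <- function() invisible(TRUE)
  s$discard <- function() { s$objects <- list(); invisible(NULL) }
  class(s) <- "fq_sink"
  s
}

# retry wrapper: transient sink failures are retried with backoff before the
# error is surfaced together with the offending object's name
sink_put_retry <- function(sink, name, data, retries = 3L) {
  for (attempt in seq_len(retries)) {
    ok <- tryCatch({ sink$put(name, data); TRUE },
                   error = function(e) {
                     if (attempt == retries) {
                       fq_sink_error(sprintf("sink failed for object '%s': %s",
                                             name, conditionMessage(e)),
                                     object = name)
                     }
                     FALSE
                   })
    if (ok) return(invisible(NULL))
    Sys.sleep(0.01 * 2^(attempt - 1L))
  }
}
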