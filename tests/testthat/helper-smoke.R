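# Shared tiny-overfit fixture: one small FED-UNet++ trained on eight 64x64
# phantoms, memoized per test session (several tests evaluate the same
# checkpoint). Conditions: widths (8, 16, 32, 64, 128), 30 epochs, Adam 1e-3
# cosine-annealed, batch size 2; phantoms use a foreground fraction of 0.03
# (a 64x64 slice at the study-scale 0.2% would leave ~8 foreground pixels,
# below any network's granularity) with contrast 180, blur 0.8, noise 8.

.smoke_env <- new.env(parent = emptyenv())

smoke_phantom_spec <- function(seed = 1L) {
  phantom_spec(image_size = 64L, fg_fraction = 0.03, contrast = 180,
               blur_sigma = 0.8, noise_sigma = 8, seed = seed)
}

smoke_fixture <- function() {
  if (!is.null(.smoke_env$fix)) return(.smoke_env$fix)
  dir <- file.path(tempdir(), "fedunetpp-smoke-ds")
  make_dataset(12L, smoke_phantom_spec(1L),
               split = c(train = 2 / 3, test = 1 / 3), out_dir = dir)
  out <- file.path(tempdir(), "fedunetpp-smoke-run")
  res <- cmd_train(list(
    data_dir = dir, out_dir = out,
    network = list(widths = c(8L, 16L, 32L, 64L, 128L)),
    epochs = 30L, batch_size = 2L, lr_init = 1e-3, lr_min = 1e-5,
    weight_decay = 1e-4, seed = 1L
  ))
  train_rep <- cmd_eval(res$checkpoint, dir, split = "train")
  .smoke_env$fix <- list(data_dir = dir, checkpoint = res$checkpoint,
                         log = res$log, train_report = train_rep)
  .smoke_env$fix
}
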