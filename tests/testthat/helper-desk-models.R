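# Desk-scale study fixtures used by the acceptance-level tests: a 1,500-image
# bimodal world at 32 px, one trained unsupervised model instance, and a
# supervised classifier. Built once per test run.

desk_world <- function(...) world_config(image_size = 32L, master_seed = 42L, ...)

desk_dataset <- function() {
  fixture("desk_dataset", function() {
    generate_dataset(desk_world(), n = 2500, seed = 424L)
  })
}

desk_vae <- function() {
  fixture("desk_vae", function() {
    train_pixelvae(desk_dataset(), pixelvae_config("desk"), seed = 1L)
  })
}

desk_latents <- function() {
  fixture("desk_latents", function() {
    encode_latents(desk_vae(), desk_dataset()$images)
  })
}

desk_axis <- function() {
  fixture("desk_axis", function() {
    fit_gloss_classifier(desk_latents(),
                         desk_dataset()$manifest$gloss_label, split_seed = 77L)
  })
}

desk_supervised <- function() {
  fixture("desk_supervised", function() {
    train_supervised_classifier(desk_dataset(), supervised_config("desk"),
                                seed = 1L)
  })
}

desk_sup_features <- function() {
  fixture("desk_sup_features", function() {
    supervised_features(desk_supervised(), desk_dataset()$images)
  })
}
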