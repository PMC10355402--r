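# package-wide constants (file named to load before the modules that use
# them at top level)

.age_groups <- c("<=18", "19-29", "30-39", ">=40")

.bot_categories <- c("overall", "astroturf", "fake_follower", "self_declared",
                     "financial", "spammer")
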