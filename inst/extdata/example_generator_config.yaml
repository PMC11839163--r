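# Example generator configuration override. Fields absent here keep the
# defaults of default_generator_config(); load with
#   read_config(system.file("extdata", "example_generator_config.yaml",
#                           package = "neurogluflow"), kind = "generator")
noise_sd: 2.4          # pA per channel (0.2 uM at 12 pA/uM)
artifact_rate: 0.5     # shared rectangular artifacts per minute
electrode:
  sensitivity: 9.5     # pA/uM
  da_response: 0.47    # pA; > 0.1 pA triggers dopamine normalization
phenotypes:
  ST:
    single_peak_prob: 0.15
    turn_prob: 0.7
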