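# example run configuration for the glymphsim CLI
scenario = "bradycardia"
years = 50               # horizon, years
dt = 1                   # step, days
record_stride = 1        # record every day
output_dir = "."
formats = ["csv", "json"]
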