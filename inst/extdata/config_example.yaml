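# Example run configuration: current Swedish programme, default
# synthetic parameters and life table.
programme: current
n: 100000
runs: 5
seed: 1
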