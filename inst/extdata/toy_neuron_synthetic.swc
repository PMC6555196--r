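# synthetic toy neuron (not a reconstruction): soma, bifurcating dendrite, axon
# id type x y z radius parent
1 1 0 0 0 8 -1
2 3 12 0 0 1.5 1
3 3 40 0 0 1.2 2
4 3 70 15 0 1.0 3
5 3 70 -15 0 1.0 3
6 3 100 30 0 0.8 4
7 3 100 -30 0 0.8 5
8 2 -10 0 0 1.0 1
9 2 -60 0 0 1.0 8
10 2 -120 0 0 1.0 9
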