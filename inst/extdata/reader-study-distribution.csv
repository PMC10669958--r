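observer,arm,absence,presence
Observer 1,unaided,15302,4634
Observer 1,aided,14225,5711
Observer 2,unaided,14756,5180
Observer 2,aided,14253,5683
Observer 3,unaided,11604,8332
Observer 3,aided,13584,6352
Ground Truth,both,13928,6008
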