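ear,frequency_hz,threshold_db_hl
binaural-mean,125,5
binaural-mean,250,5
binaural-mean,500,10
binaural-mean,1000,20
binaural-mean,2000,35
binaural-mean,3000,45
binaural-mean,4000,50
binaural-mean,6000,60
binaural-mean,8000,65
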