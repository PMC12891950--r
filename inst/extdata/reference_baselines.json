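{
 "lr91_deriv_at_rest": [
  -0.0018711455537665511,
  -2.0534189992815755e-07,
  2.8230034369658777e-06,
  1.8245149126874544e-06,
  -1.9051730295097363e-07,
  2.393125896732902e-07,
  -0.00015862033648600437,
  -4.860538707948812e-09
 ],
 "tt06_deriv_at_rest": [
  -0.0012549791184469083,
  1.6037349326071364e-05,
  4.442200955841882e-05,
  -1.7839620542975356e-07,
  -7.886450723795889e-07,
  -1.6016246460516635e-05,
  0.0004456012298255439,
  -0.00012738141383296332,
  -2.9927388045425247e-05,
  -7.75852497439026e-05,
  -0.004310364726149858,
  6.590134545801703e-05,
  0.0005297821087279228,
  -2.1035033907965473e-08,
  0.0010592846780493991,
  0.0003010426160896477,
  5.6940655419425113e-05,
  -1.8582318976448507e-08,
  -8.92302474585256e-12
 ],
 "lr91_quiescent_v": -84.55157804726775,
 "lr91_quiescent_v_ko12.5": -64.50895566613461,
 "tt06_quiescent_v": -85.90633508120379,
 "lr91_baseline": {
  "rmp": -84.4432200530198,
  "peak": 43.21365113847027,
  "apa": 127.65687119149007,
  "dvdtmax": 424.17063446985253,
  "apd90": 361.473148242296,
  "apd50": 271.0220586619738
 },
 "tt06_baseline": {
  "rmp": -85.50806686844695,
  "peak": 38.681095183661,
  "apa": 124.18916205210795,
  "dvdtmax": 360.84761615736164,
  "apd90": 306.10670617303106,
  "apd50": 277.9014768127345
 }
}
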