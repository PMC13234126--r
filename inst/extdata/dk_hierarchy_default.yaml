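groups:
- coarse_id: 1
  name: lh_cerebral_wm
  final_ids: 1
  terminal: yes
- coarse_id: 2
  name: rh_cerebral_wm
  final_ids: 2
  terminal: yes
- coarse_id: 3
  name: lh_deep
  final_ids:
  - 3
  - 4
  - 5
  - 6
  - 7
  - 8
  - 9
  - 10
  - 11
  - 12
  - 13
  - 14
  - 15
  terminal: no
- coarse_id: 4
  name: rh_deep
  final_ids:
  - 16
  - 17
  - 18
  - 19
  - 20
  - 21
  - 22
  - 23
  - 24
  - 25
  - 26
  - 27
  - 28
  terminal: no
- coarse_id: 5
  name: lh_cortical
  final_ids:
  - 29
  - 30
  - 31
  - 32
  - 33
  - 34
  - 35
  - 36
  - 37
  - 38
  - 39
  - 40
  - 41
  - 42
  - 43
  - 44
  - 45
  - 46
  - 47
  - 48
  - 49
  - 50
  - 51
  - 52
  - 53
  - 54
  - 55
  - 56
  - 57
  - 58
  - 59
  - 60
  - 61
  - 62
  terminal: no
- coarse_id: 6
  name: rh_cortical
  final_ids:
  - 63
  - 64
  - 65
  - 66
  - 67
  - 68
  - 69
  - 70
  - 71
  - 72
  - 73
  - 74
  - 75
  - 76
  - 77
  - 78
  - 79
  - 80
  - 81
  - 82
  - 83
  - 84
  - 85
  - 86
  - 87
  - 88
  - 89
  - 90
  - 91
  - 92
  - 93
  - 94
  - 95
  - 96
  terminal: no
- coarse_id: 7
  name: midline
  final_ids:
  - 97
  - 98
  - 99
  - 100
  - 101
  terminal: no
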