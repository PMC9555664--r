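year,wnao
2002,-0.245759676176587
2003,0.00313218524672322
2004,-0.779681425856181
2005,-1.15334876098524
2006,-0.0769282362170708
2007,-2.54765283820066
2008,0.135336502088532
2009,0.00848535620565135
2010,-1.97612152892193
2011,2.32912475447391
2012,0.590884573439105
2013,0.586141173053762
2014,-0.366568095704014
2015,0.537327560045628
2016,-0.877702831513703
2017,0.995839894684232
2018,-0.958141376660634
2019,1.82214707157288
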