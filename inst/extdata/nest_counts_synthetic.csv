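year,species,region,nest_starts
2009,Great Egret,all-WCAs,5200
2010,Great Egret,all-WCAs,6000
2010,White Ibis,all-WCAs,12000
2011,Great Egret,all-WCAs,6500
2011,White Ibis,all-WCAs,18000
2011,Wood Stork,all-WCAs,1200
2012,Great Egret,all-WCAs,5800
2012,White Ibis,all-WCAs,9000
2012,Wood Stork,all-WCAs,0
2013,Great Egret,all-WCAs,6200
2013,White Ibis,all-WCAs,14000
2013,Wood Stork,all-WCAs,800
2014,Great Egret,all-WCAs,7000
2014,White Ibis,all-WCAs,21000
2014,Wood Stork,all-WCAs,1500
2015,Great Egret,all-WCAs,6400
2015,Wood Stork,all-WCAs,900
2016,Great Egret,all-WCAs,5900
2016,Wood Stork,all-WCAs,700
2017,Great Egret,all-WCAs,7200
2017,Wood Stork,all-WCAs,1100
2018,Great Egret,all-WCAs,10000
2018,White Ibis,all-WCAs,55000
2018,Wood Stork,all-WCAs,2500
2011,Egretta_group,WCA-3A,260
2012,Egretta_group,WCA-3A,240
2013,Egretta_group,WCA-3A,300
2014,Egretta_group,WCA-3A,280
2018,Egretta_group,WCA-3A,420
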